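#' Construct and validate a differential-expression table
#'
#' A DE table is a plain `data.frame` with one row per gene and columns
#' `gene` (unique non-empty strings), `log2fc` (log2 fold change oriented
#' wild-type over knockout, so positive values mean the perturbed factor
#' upregulates the gene), `padj` (adjusted P in `[0,1]`, may be `NA` when the
#' DE engine filtered the gene independently) and `base_mean` (non-negative
#' mean expression, may be `NA`).
#'
#' @param gene character vector of gene identifiers.
#' @param log2fc numeric log2 fold changes (WT/KO orientation).
#' @param padj adjusted P values in `[0,1]`, `NA` allowed.
#' @param base_mean non-negative mean expression, `NA` allowed.
#' @return a validated `data.frame` with the four columns above.
#' @seealso [read_de_table()]
#' @export
de_table <- function(gene, log2fc, padj = NA_real_, base_mean = NA_real_) {
  d <- data.frame(gene = as.character(gene), log2fc = as.numeric(log2fc),
                  padj = as.numeric(padj), base_mean = as.numeric(base_mean),
                  stringsAsFactors = FALSE)
  validate_de_table(d)
}

validate_de_table <- function(d) {
  req <- c("gene", "log2fc", "padj")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(sprintf("DE table is missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!"base_mean" %in% names(d)) d$base_mean <- NA_real_
  d$gene <- as.character(d$gene)
  if (any(!nzchar(d$gene) | is.na(d$gene)))
    stop("DE table contains empty gene identifiers", call. = FALSE)
  dup <- unique(d$gene[duplicated(d$gene)])
  if (length(dup))
    stop(sprintf("duplicated gene identifier(s): %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  bad <- !is.na(d$padj) & (d$padj < 0 | d$padj > 1)
  if (any(bad))
    stop("padj values outside [0, 1]", call. = FALSE)
  if (any(!is.na(d$base_mean) & d$base_mean < 0))
    stop("negative base_mean values", call. = FALSE)
  d[c("gene", "log2fc", "padj", "base_mean")]
}

#' Read a differential-expression table from TSV
#'
#' Expects a header with at least gene, log2fc and padj columns; column names
#' are configurable so tables from any DE engine can be consumed.  Rows with
#' unparseable log2fc or padj are kept with those fields `NA` (they are
#' excluded from the statistics that need them).  Fold changes are oriented
#' wild-type over knockout; if the file is oriented the other way, pass
#' `orientation = "ko_wt"` to negate log2fc on load.
#'
#' @param path TSV file path.
#' @param columns named character vector mapping the internal names
#'   `gene`, `log2fc`, `padj`, `base_mean` to the file's column names.
#' @param orientation `"wt_ko"` (default, kept as is) or `"ko_wt"`
#'   (log2fc negated on load).
#' @param quiet suppress the row-count message.
#' @return a validated DE `data.frame` (see [de_table()]).
#' @export
read_de_table <- function(path,
                          columns = c(gene = "gene", log2fc = "log2fc",
                                      padj = "padj", base_mean = "base_mean"),
                          orientation = c("wt_ko", "ko_wt"),
                          quiet = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (f in c("gene", "log2fc", "padj")) {
    cn <- if (f %in% names(columns)) columns[[f]] else f
    if (!cn %in% names(raw))
      stop(sprintf("missing required column `%s` in %s", cn, path),
           call. = FALSE)
  }
  bm_col <- if ("base_mean" %in% names(columns)) columns[["base_mean"]] else "base_mean"
  d <- data.frame(
    gene = as.character(raw[[columns[["gene"]]]]),
    log2fc = suppressWarnings(as.numeric(raw[[columns[["log2fc"]]]])),
    padj = suppressWarnings(as.numeric(raw[[columns[["padj"]]]])),
    base_mean = if (bm_col %in% names(raw))
      suppressWarnings(as.numeric(raw[[bm_col]])) else NA_real_,
    stringsAsFactors = FALSE)
  if (orientation == "ko_wt") d$log2fc <- -d$log2fc
  d <- validate_de_table(d)
  if (!quiet)
    message(sprintf("read %d gene records from %s (%d with missing log2fc, %d with missing padj)",
                    nrow(d), path, sum(is.na(d$log2fc)), sum(is.na(d$padj))))
  d
}

#' Write a DE table as TSV
#' @param d DE table (see [de_table()]).
#' @param path output file.
#' @export
write_de_table <- function(d, path) {
  d <- validate_de_table(d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TPM expression matrix from TSV
#'
#' First column gene identifiers, remaining columns one sample each,
#' entries in transcripts-per-million units (non-negative).
#'
#' @param path TSV file path.
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_tpm_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(genes))
    stop("duplicated gene identifiers in TPM matrix", call. = FALSE)
  if (any(m < 0, na.rm = TRUE))
    stop("negative TPM entries", call. = FALSE)
  rownames(m) <- genes
  m
}

#' Expression filter: genes detected above a TPM floor in enough samples
#'
#' Keeps genes with TPM of at least `min_tpm` in at least `min_samples`
#' samples (defaults: minimum TPM of 1 in at least 3 samples, the filter the
#' pipeline applies to each bulk dataset before merging).
#'
#' @param tpm numeric matrix, genes x samples, rownames = gene ids.
#' @param min_tpm TPM floor (`>=` comparison).
#' @param min_samples minimum number of samples at or above the floor.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(tpm, min_tpm = 1, min_samples = 3) {
  if (!is.matrix(tpm) || is.null(rownames(tpm)))
    stop("`tpm` must be a matrix with gene rownames", call. = FALSE)
  if (min_samples > ncol(tpm))
    stop_param("min_samples",
               sprintf("%d exceeds the sample count (%d)", min_samples, ncol(tpm)))
  keep <- rowSums(tpm >= min_tpm, na.rm = TRUE) >= min_samples
  rownames(tpm)[keep]
}

#' Merge two DE tables by gene name
#'
#' Inner join on exact, case-sensitive gene-id equality; per-dataset columns
#' are suffixed with the dataset labels.  Genes present in only one table are
#' dropped (their count is reported via `message()` unless `quiet`).
#'
#' @param a,b DE tables.
#' @param labels length-2 character vector naming the datasets; column
#'   suffixes in the result.
#' @param quiet suppress the drop-count message.
#' @return a `data.frame` with columns `gene`, `log2fc_<A>`, `padj_<A>`,
#'   `log2fc_<B>`, `padj_<B>`; attribute `labels` carries the dataset labels.
#' @export
merge_by_gene <- function(a, b, labels = c("A", "B"), quiet = FALSE) {
  a <- validate_de_table(a); b <- validate_de_table(b)
  stopifnot(length(labels) == 2L, !anyDuplicated(labels))
  common <- intersect(a$gene, b$gene)
  if (length(common) == 0L)
    stop("no genes shared between the two tables (empty merge)", call. = FALSE)
  if (!quiet) {
    message(sprintf("merged %d genes; dropped %d only in %s, %d only in %s",
                    length(common), nrow(a) - length(common), labels[1L],
                    nrow(b) - length(common), labels[2L]))
  }
  ia <- match(common, a$gene); ib <- match(common, b$gene)
  out <- data.frame(gene = common,
                    la = a$log2fc[ia], pa = a$padj[ia],
                    lb = b$log2fc[ib], pb = b$padj[ib],
                    stringsAsFactors = FALSE)
  names(out) <- c("gene",
                  paste0("log2fc_", labels[1L]), paste0("padj_", labels[1L]),
                  paste0("log2fc_", labels[2L]), paste0("padj_", labels[2L]))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

merged_cols <- function(merged, label) {
  lc <- paste0("log2fc_", label); pc <- paste0("padj_", label)
  if (!all(c(lc, pc) %in% names(merged)))
    stop(sprintf("dataset label `%s` not found in merged table", label),
         call. = FALSE)
  list(log2fc = merged[[lc]], padj = merged[[pc]])
}

#' Regulated-gene-set definition
#'
#' Upregulated genes are those with log2 fold change (WT/KO) above
#' `lfc_threshold` and adjusted P below `alpha`; downregulated genes those
#' with log2 fold change below `-lfc_threshold` and adjusted P below `alpha`.
#' All comparisons are strict, so boundary values are excluded, and records
#' with missing padj or log2fc never qualify.
#'
#' @param d DE table.
#' @param direction `"up"` or `"down"`.
#' @param alpha adjusted-P cutoff, in (0, 1); default 0.05.
#' @param lfc_threshold absolute log2 fold-change cutoff; default 0 (any
#'   change in the right direction).  The Gene-Ontology-input dialect of the
#'   downregulated definition uses 0.1.
#' @return character vector of gene ids.
#' @export
classify_regulated <- function(d, direction = c("up", "down"),
                               alpha = 0.05, lfc_threshold = 0) {
  direction <- match.arg(direction)
  d <- validate_de_table(d)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop_param("alpha", "must be a single value in (0, 1)")
  if (lfc_threshold < 0)
    stop_param("lfc_threshold", "must be non-negative")
  ok <- !is.na(d$padj) & !is.na(d$log2fc) & d$padj < alpha
  sel <- if (direction == "up") ok & d$log2fc > lfc_threshold
         else                   ok & d$log2fc < -lfc_threshold
  d$gene[sel]
}

#' Read gene sets from GMT or two-column TSV
#'
#' GMT: one set per line, `name<TAB>description<TAB>member...`.  Two-column
#' TSV: header `set<TAB>gene`, one membership per row.  A gene may belong to
#' several sets (cell-cycle phase lists allow multi-phase membership).
#'
#' @param path file path; format inferred from the `.gmt` extension unless
#'   `format` is given.
#' @param format `"gmt"` or `"tsv"`.
#' @return named list of character vectors (a gene-set collection).
#' @export
read_gene_sets <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  format <- match.arg(format, c("gmt", "tsv"))
  sets <- if (format == "gmt") {
    fgsea::gmtPathways(path)
  } else {
    d <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 2L)
      stop("two-column gene-set TSV needs columns <set>, <gene>", call. = FALSE)
    split(as.character(d[[2L]]), d[[1L]])
  }
  if (anyDuplicated(names(sets)))
    stop("duplicated set names in gene-set file", call. = FALSE)
  lapply(sets, function(g) unique(as.character(g[nzchar(g)])))
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set description column (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype-by-EdU count table from CSV
#'
#' Expects columns `group`, `edu_pos`, `edu_neg` (non-negative integers,
#' each group total at least 1).
#'
#' @param path CSV file path.
#' @return validated count `data.frame`.
#' @export
read_edu_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_edu_table(d)
}

validate_edu_table <- function(d) {
  req <- c("group", "edu_pos", "edu_neg")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(sprintf("count table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  d$group <- as.character(d$group)
  if (anyDuplicated(d$group)) stop("duplicated group labels", call. = FALSE)
  if (nrow(d) < 2L) stop("need at least 2 groups", call. = FALSE)
  cnt <- c(d$edu_pos, d$edu_neg)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(d$edu_pos + d$edu_neg < 1))
    stop("each group needs a total count of at least 1", call. = FALSE)
  d[req]
}
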