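#' Read a methylation beta matrix with its probe annotation
#'
#' The beta matrix is a TSV whose first column (`site_id`) holds CpG probe
#' identifiers and whose remaining columns are samples; cells are methylation
#' fractions in \[0, 1\]. Non-numeric cells (e.g. `"NA"`, `"."`) are parsed as
#' missing. The annotation TSV must carry at least `site_id` and
#' `gene_symbol` columns; multi-gene probes written as `"GENE1;GENE2"` are
#' resolved to the first listed symbol (with a warning), so the site-to-gene
#' map used downstream is one-to-one.
#'
#' @param path Path to the beta-matrix TSV.
#' @param annotation_path Path to the probe annotation TSV.
#' @return A list with elements `beta` (numeric matrix, sites x samples, with
#'   row/column names) and `annotation` (data.frame with columns `site_id`,
#'   `gene_symbol` and, when present, `chromosome`, `position`).
#' @export
read_beta_matrix <- function(path, annotation_path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("beta matrix needs a site_id column plus >=1 sample")
  site_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(site_ids))
    stop("duplicate site ids in beta matrix: ",
         paste(unique(site_ids[duplicated(site_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in beta matrix: ",
         paste(unique(sample_ids[duplicated(sample_ids)])[1:3], collapse = ", "))
  values <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) values <- matrix(values, nrow = 1L)
  dimnames(values) <- list(site_ids, sample_ids)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("beta value out of [0,1] at site %s, sample %s",
                 site_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  annotation <- read_site_annotation(annotation_path)
  list(beta = values, annotation = annotation)
}

#' @rdname read_beta_matrix
#' @export
read_site_annotation <- function(annotation_path) {
  ann <- utils::read.delim(annotation_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("site_id", "gene_symbol")
  if (!all(need %in% colnames(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  multi <- grepl(";", ann$gene_symbol, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-gene probe(s); keeping first listed symbol")
    ann$gene_symbol[multi] <- vapply(
      strsplit(ann$gene_symbol[multi], ";", fixed = TRUE), `[`, "", 1L)
  }
  keep <- intersect(c("site_id", "gene_symbol", "chromosome", "position"),
                    colnames(ann))
  ann[keep]
}

#' Write a beta matrix to TSV
#'
#' Values are written with full double precision so that a read/write/read
#' round trip is bit-exact for decimal inputs.
#'
#' @param beta Numeric sites x samples matrix with dimnames.
#' @param path Output TSV path.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(site_id = rownames(beta),
                   format(beta, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expected TSV header: `sample_id group event time age stage_T stage_N
#' stage_M`. `event` must be 0/1, `time` >= 0 (days), stages ordinal
#' integers (T1..T4 -> 1..4, N0..N2 -> 0..2, M0/M1 -> 0/1; sub-stages such
#' as "N1a" are truncated to their integer part when coded as text).
#'
#' @param path Path to the clinical TSV.
#' @return A validated data.frame.
#' @export
read_clinical <- function(path) {
  clin <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "event", "time")
  if (!all(need %in% colnames(clin)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(clin$sample_id)) stop("duplicate sample ids in clinical table")
  for (col in c("stage_T", "stage_N", "stage_M"))
    if (col %in% colnames(clin) && is.character(clin[[col]]))
      clin[[col]] <- parse_stage(clin[[col]])
  ok <- is.na(clin$event) | clin$event %in% c(0, 1)
  if (!all(ok)) stop("event must be 0/1; offending sample: ",
                     clin$sample_id[!ok][1L])
  if (any(clin$time < 0, na.rm = TRUE)) stop("negative follow-up time")
  clin
}

# "T2" -> 2, "N1a" -> 1, "M0" -> 0; plain integers pass through
parse_stage <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  txt <- is.na(out) & !is.na(x) & nzchar(x)
  out[txt] <- suppressWarnings(as.numeric(sub("^[A-Za-z]+([0-9]+).*$", "\\1",
                                              x[txt])))
  out
}

#' Write a clinical table to TSV
#' @param clin Clinical data.frame.
#' @param path Output path.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prior gene regulatory network from a CSV edge list
#'
#' The first two columns (configurable) are taken as gene symbols of an
#' undirected edge. A header row is auto-detected from common column-name
#' tokens ("source", "target", "from", "to", ...), or can be forced with
#' `header`. Self-loops are dropped and duplicate edges (in either
#' orientation) collapsed.
#'
#' @param path Path to the CSV edge list.
#' @param columns Integer pair: source/target column indices (default 1:2).
#' @param header `NULL` to auto-detect, otherwise TRUE/FALSE.
#' @param sep Field separator (default comma).
#' @return An object of class `prior_network`: list with `edges` (data.frame
#'   `gene_a`, `gene_b`) and `source` tag.
#' @export
read_prior_network <- function(path, columns = c(1L, 2L), header = NULL,
                               sep = ",") {
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE, fill = TRUE,
                           comment.char = "", quote = "\"")
  if (max(columns) > ncol(raw)) stop("edge-list columns out of range")
  header_tokens <- c("source", "target", "from", "to", "gene_a", "gene_b",
                     "gene1", "gene2", "node1", "node2", "genea", "geneb",
                     "symbol1", "symbol2", "regulator", "regulated")
  if (is.null(header)) {
    first <- tolower(trimws(as.character(raw[1L, columns])))
    header <- all(first %in% header_tokens)
  }
  if (isTRUE(header)) raw <- raw[-1L, , drop = FALSE]
  a <- trimws(as.character(raw[[columns[1L]]]))
  b <- trimws(as.character(raw[[columns[2L]]]))
  keep <- nzchar(a) & nzchar(b) & !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  prior_network(data.frame(gene_a = a, gene_b = b,
                           stringsAsFactors = FALSE),
                source = basename(path))
}

#' Construct a prior network from an in-memory edge data.frame
#'
#' @param edges Data.frame whose first two columns are gene symbols.
#' @param source Free-text provenance tag.
#' @return A `prior_network` object.
#' @export
prior_network <- function(edges, source = "in-memory") {
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  edges <- data.frame(gene_a = lo[!dup], gene_b = hi[!dup],
                      stringsAsFactors = FALSE)
  if (nrow(edges) < 1L) stop("prior network has no edges after cleaning")
  structure(list(edges = edges, source = source), class = "prior_network")
}

#' @export
print.prior_network <- function(x, ...) {
  nodes <- unique(c(x$edges$gene_a, x$edges$gene_b))
  cat(sprintf("prior_network: %d genes, %d undirected edges (source: %s)\n",
              length(nodes), nrow(x$edges), x$source))
  invisible(x)
}
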