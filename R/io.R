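## Standard-format I/O: GFF3 (1-based closed) for gene annotation,
## bedGraph (0-based half-open) per strand/replicate/time point for
## coverage, Newick for trees, TSV for matrices and tables.  Internal
## coordinates are 0-based half-open; conversion happens here only.

#' Write a gene annotation as GFF3
#'
#' @param annotation annotation data frame (0-based half-open `start`,
#'   `end`, `strand`, `gene_id`, optional `dup_group`).
#' @param path output file.
#' @param seqname sequence name (default "genome").
#' @export
write_gff3 <- function(annotation, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  if (!is.null(annotation$dup_group))
    S4Vectors::mcols(gr)$dup_group <- annotation$dup_group
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' @param path GFF3 file.
#' @return Annotation data frame with 0-based half-open coordinates.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  dg <- S4Vectors::mcols(gr)$dup_group
  data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr),
    dup_group = if (is.null(dg)) NA_integer_ else as.integer(dg),
    stringsAsFactors = FALSE)
}

#' Write one coverage vector as bedGraph
#'
#' @param track per-nucleotide coverage vector.
#' @param path output file.
#' @param seqname sequence name.
#' @export
write_bedgraph <- function(track, path, seqname = "genome") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = starts + 1L, end = ends),
    score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a coverage vector
#'
#' @param path bedGraph file.
#' @param genome_length expected vector length.
#' @return Numeric per-nucleotide coverage vector.
#' @export
read_bedgraph <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  v <- numeric(genome_length)
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sc <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) v[st[i]:en[i]] <- sc[i]
  v
}

#' Write all tracks of a coverage experiment
#'
#' One bedGraph per (time point, replicate, strand), named
#' `cov_t<T>_r<R>_<plus|minus>.bedGraph`.
#'
#' @param experiment a `coverage_experiment`.
#' @param dir output directory (created if needed).
#' @export
write_coverage_tracks <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(experiment$n_timepoints))
    for (r in seq_len(experiment$n_replicates))
      for (s in c("+", "-")) {
        nm <- sprintf("cov_t%d_r%d_%s.bedGraph", t, r,
                      if (s == "+") "plus" else "minus")
        write_bedgraph(experiment$tracks[[t]][[r]][[s]], file.path(dir, nm))
      }
  invisible(dir)
}

#' Write an expression matrix as TSV (plus a QC table)
#'
#' @param em an `expression_matrix`.
#' @param path expression TSV path; the QC table (retained fraction,
#'   fallback flags) goes to `<path>.qc.tsv`.
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  qc <- data.frame(gene_id = rownames(em$values),
                   retained_fraction = em$retained_fraction,
                   fallback_any = apply(em$fallback, 1, any),
                   stringsAsFactors = FALSE)
  utils::write.table(qc, paste0(path, ".qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' @param path TSV written by [write_expression_tsv()].
#' @param n_timepoints,n_replicates design dimensions.
#' @return An `expression_matrix` (without retention metadata).
#' @export
read_expression_tsv <- function(path, n_timepoints = 5L, n_replicates = 3L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  structure(list(values = values,
                 layout = .sample_layout(n_timepoints, n_replicates),
                 retained_fraction = rep(NA_real_, nrow(values)),
                 fallback = matrix(FALSE, nrow(values), n_timepoints),
                 annotation = NULL),
            class = "expression_matrix")
}

#' Write / read a conservation matrix as TSV
#'
#' @param conservation genes x species 0/1 matrix.
#' @param path TSV path.
#' @export
write_conservation_tsv <- function(conservation, path) {
  df <- data.frame(gene_id = rownames(conservation), conservation,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conservation_tsv
#' @export
read_conservation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
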