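COORD_COMMENT <- "# coordinates: 1-based inclusive; chromosomes ordered as configured"

## Shared writer: tab-separated with a coordinate-convention comment header.
write_tsv_commented <- function(df, path, comment = COORD_COMMENT) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write / read a methylation matrix as TSV
#'
#' Layout: comment line stating the coordinate convention, then a header row
#' `chrom, pos, site_id` followed by one column per sample. Round-trips are
#' stable to the text precision used (15 significant digits).
#'
#' @param study a `MethylationStudy` (writer) or path (reader).
#' @param path file path.
#' @return the path (writer); a list with `sites` and `values` (reader).
#' @export
write_methylation_tsv <- function(study, path) {
  df <- cbind(study$sites[, c("chrom", "pos", "site_id")],
              as.data.frame(format(study$values, digits = 15, trim = TRUE)))
  write_tsv_commented(df, path)
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("chrom", "pos", "site_id")
  if (!all(need %in% names(df)[1:3]))
    stopf("header must start with: %s", paste(need, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(!is.finite(pos) | pos < 1 | pos != floor(pos))
  if (length(bad) > 0L)
    stopf("malformed position at data line %d (value '%s'); positions must be positive integers",
          bad[1], df$pos[bad[1]])
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key))
    stopf("duplicate (chrom, pos) at data line %d: %s",
          which(duplicated(key))[1], key[duplicated(key)][1])
  sample_cols <- setdiff(names(df), need)
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(vals)) {
    nonnum <- which(!apply(df[, sample_cols, drop = FALSE], 1,
                           function(r) all(is.finite(suppressWarnings(as.numeric(r))))))
    stopf("malformed numeric value at data line %d", nonnum[1])
  }
  storage.mode(vals) <- "double"
  list(sites = data.frame(chrom = as.character(df$chrom),
                          pos = as.integer(df$pos),
                          site_id = df$site_id, stringsAsFactors = FALSE),
       values = vals)
}

#' Write / read a reference panel as TSV
#'
#' @param panel a [reference_panel()] (writer) or path (reader).
#' @param path file path.
#' @return path (writer) / `ReferencePanel` (reader).
#' @export
write_panel_tsv <- function(panel, path) {
  df <- cbind(panel$sites[, c("chrom", "pos", "site_id")],
              as.data.frame(panel$profile))
  write_tsv_commented(df, path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- read_tsv_commented(path)
  cts <- setdiff(names(df), c("chrom", "pos", "site_id", "discriminating"))
  reference_panel(
    data.frame(chrom = as.character(df$chrom), pos = as.integer(df$pos),
               site_id = df$site_id, stringsAsFactors = FALSE),
    as.matrix(df[, cts, drop = FALSE]), cts)
}

#' Write covariates and phenotype as TSV
#'
#' @param study a `MethylationStudy`.
#' @param path file path.
#' @return the path.
#' @export
write_covariates_tsv <- function(study, path) {
  df <- data.frame(sample_id = colnames(study$values),
                   study$covariates,
                   phenotype_raw = study$phenotype_raw,
                   row.names = NULL)
  write_tsv_commented(df, path, comment = "# per-sample covariates and raw phenotype")
}

#' Write estimated cell proportions as TSV
#'
#' @param props a `CellProportions`.
#' @param path file path.
#' @return the path.
#' @export
write_proportions_tsv <- function(props, path) {
  df <- data.frame(sample_id = rownames(props$values) %||%
                     sprintf("s%03d", seq_len(nrow(props$values))),
                   as.data.frame(props$values),
                   residual_norm = props$residual_norm %||% NA_real_,
                   row.names = NULL)
  write_tsv_commented(df, path, comment = "# per-sample cell-type proportions (unit simplex)")
}

#' Write / read gene models as BED
#'
#' On disk BED is 0-based half-open; internal coordinates are 1-based
#' inclusive. The conversion happens only here, through rtracklayer.
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive) for the writer; a path for the reader.
#' @param path file path.
#' @return path (writer) / genes data.frame in internal convention (reader).
#' @export
write_gene_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    name = genes$gene_id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),   # rtracklayer yields 1-based
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write / read gene sets as GMT
#'
#' GMT: one set per line, `set_id <TAB> description <TAB> member...`. Reading
#' goes through fgsea's parser.
#'
#' @param gene_sets named list of character vectors (writer) or path (reader).
#' @param path file path.
#' @return path (writer) / named list (reader).
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(id)
    paste(c(id, "na", gene_sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
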