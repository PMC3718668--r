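#' Write a table as TSV with commented metadata header
#'
#' @param df data.frame.
#' @param path Output file.
#' @param meta Named list written as `# key: value` header lines.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, as.character(meta[[k]])), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path File path.
#' @return data.frame; header metadata in attribute `"meta"`.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    k <- sub(":.*$", "", kv)
    meta[[k]] <- sub("^[^:]*:\\s*", "", kv)
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write loci or fragments as BED
#'
#' Site tables become 6-column BED (name = category, score = partner
#' offset d); fragment tables become BED6+ (name = scenario:category,
#' score = length, strand = ".").
#'
#' @param x data.frame from [scan_cnnr_loci()], [call_sites()] or a
#'   fragment table.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  n <- nrow(x)
  if (!is.null(x$pos)) {
    score <- if (!is.null(x$partner_offset_d))
      ifelse(is.na(x$partner_offset_d), 0L, x$partner_offset_d)
    else rep(0L, n)
    name <- if (!is.null(x$category)) x$category else rep(".", n)
    bed <- data.frame(x$chrom, x$pos, x$pos + 1L, name, score, x$strand)
  } else {
    nm <- if (n) paste0(x$scenario, ":",
                        ifelse(is.na(x$category), ".", x$category))
      else character(0)
    bed <- data.frame(x$chrom, x$start, x$end, nm, x$length,
                      rep(".", n))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED3..BED6 file.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:6],
                          fill = TRUE)
  df <- df[, colSums(is.na(df)) < nrow(df), drop = FALSE]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

#' Read region annotations from BED or GFF3
#'
#' @param path `.bed` or `.gff`/`.gff3` file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand` and `name` where available.
#' @export
read_regions <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read GFF3")
    gr <- rtracklayer::import(path)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               name = if (!is.null(gr$ID)) as.character(gr$ID)
                 else as.character(seq_along(gr)),
               stringsAsFactors = FALSE)
  } else {
    df <- read_bed(path)
    if (is.null(df$strand)) df$strand <- "+"
    if (is.null(df$name)) df$name <- as.character(seq_len(nrow(df)))
    df
  }
}

#' Write gene models as GFF3
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`,
#'   `name`.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tmspjiseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, genes$name), con)
  invisible(path)
}

#' Read bisulfite-style site records
#'
#' @param path TSV with columns chrom, pos, strand, methylated_reads,
#'   total_reads (header optional metadata lines start with `#`).
#' @return data.frame.
#' @export
read_wgbs <- function(path) {
  df <- read_tsv_meta(path)
  need <- c("chrom", "pos", "strand", "methylated_reads", "total_reads")
  if (!all(need %in% names(df)))
    stop("bisulfite TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a run manifest
#'
#' Records the package version, parameters, seed and input checksums of a
#' pipeline run next to its output.
#'
#' @param out_path Output file the manifest describes (`.manifest.json`
#'   appended).
#' @param params Named list of run parameters.
#' @param inputs Character vector of input file paths (md5-summed).
#' @export
write_manifest <- function(out_path, params = list(),
                           inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool = "mspjiseq",
    version = as.character(utils::packageVersion("mspjiseq")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output = out_path,
    params = params,
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
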