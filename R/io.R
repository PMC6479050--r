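# Readers and writers for the plain-text formats the pipeline touches:
# BED3/BED6/narrowPeak, refFlat gene models, bedGraph signal, DESeq2-shaped
# expression tables.  Readers validate aggressively and report the offending
# line; on-disk coordinates follow each format's own convention (all the
# formats here are natively 0-based half-open, so no shifting occurs).

read_body_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], ln = ln[keep], n_skipped = sum(!keep))
}

parse_coord <- function(x, ln, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad))
    stop(sprintf("%s: line %d: non-integer %s '%s'", path, ln[bad[1]], what, x[bad[1]]))
  v
}

#' Read genomic intervals from BED3, BED6 or narrowPeak files
#'
#' Track/browser/comment lines are tolerated and skipped (the count of
#' skipped lines is attached as the `n_skipped` attribute).  narrowPeak
#' columns 7-10 are retained as `signal_value`, `p_value`, `q_value`,
#' `summit`; a summit of -1 is recorded as `NA` (absent).  Strand is `"."`
#' when the format carries none.
#'
#' @param path file path.
#' @param format one of `"bed3"`, `"bed6"`, `"narrowpeak"`.
#' @return interval data.frame in file order (0-based half-open).
#' @export
read_intervals <- function(path, format = c("bed3", "bed6", "narrowpeak")) {
  format <- match.arg(format)
  ncol_needed <- switch(format, bed3 = 3L, bed6 = 6L, narrowpeak = 10L)
  b <- read_body_lines(path)
  if (!length(b$lines)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- b$n_skipped
    return(out)
  }
  fields <- strsplit(b$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  if (length(bad))
    stop(sprintf("%s: line %d: expected %d tab-separated columns, found %d",
                 path, b$ln[bad[1]], ncol_needed, nf[bad[1]]))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- data.frame(
    chrom = col(1),
    start = parse_coord(col(2), b$ln, path, "start"),
    end = parse_coord(col(3), b$ln, path, "end"),
    stringsAsFactors = FALSE
  )
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop(sprintf("%s: line %d: start >= end", path, b$ln[bad[1]]))
  if (format %in% c("bed6", "narrowpeak")) {
    out$name <- col(4)
    out$score <- suppressWarnings(as.numeric(col(5)))
    strand <- col(6)
    badstr <- which(!strand %in% c("+", "-", "."))
    if (length(badstr))
      stop(sprintf("%s: line %d: unknown strand '%s'", path, b$ln[badstr[1]],
                   strand[badstr[1]]))
    out$strand <- strand
  } else {
    out$strand <- "."
  }
  if (format == "narrowpeak") {
    out$signal_value <- as.numeric(col(7))
    out$p_value <- as.numeric(col(8))
    out$q_value <- as.numeric(col(9))
    summit <- parse_coord(col(10), b$ln, path, "summit")
    summit[summit < 0] <- NA_real_
    out$summit <- summit
  }
  validate_intervals(out, path)
  attr(out, "n_skipped") <- b$n_skipped
  out
}

#' Write intervals as BED3, BED6 or narrowPeak
#'
#' @param x interval data.frame.
#' @param path output file.
#' @param format one of `"bed3"`, `"bed6"`, `"narrowpeak"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed3", "bed6", "narrowpeak")) {
  format <- match.arg(format)
  validate_intervals(x)
  nm <- if (is.null(x$name)) sprintf("peak_%d", seq_len(nrow(x))) else x$name
  sc <- if (is.null(x$score)) rep(0, nrow(x)) else x$score
  st <- if (is.null(x$strand)) rep(".", nrow(x)) else x$strand
  lines <- switch(format,
    bed3 = sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end)),
    bed6 = sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), nm, format_num(sc), st),
    narrowpeak = {
      sv <- if (is.null(x$signal_value)) rep(0, nrow(x)) else x$signal_value
      pv <- if (is.null(x$p_value)) rep(-1, nrow(x)) else x$p_value
      qv <- if (is.null(x$q_value)) rep(-1, nrow(x)) else x$q_value
      sm <- if (is.null(x$summit)) rep(NA_real_, nrow(x)) else x$summit
      sm[is.na(sm)] <- -1
      sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d",
              x$chrom, as.integer(x$start), as.integer(x$end), nm,
              format_num(sc), st, format_num(sv), format_num(pv),
              format_num(qv), as.integer(sm))
    })
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  out <- sprintf("%.6g", x)
  int <- is.finite(x) & x == floor(x) & abs(x) < 1e15
  out[int] <- sprintf("%d", as.integer(x[int]))
  out
}

#' Read refFlat gene models
#'
#' refFlat columns: geneName, name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds (exon lists comma-terminated).
#' Coordinates are 0-based half-open, kept as-is.  The declared exon count
#' must match both exon lists; exons must be sorted, non-overlapping and
#' within the transcript.
#'
#' @param path refFlat file.
#' @return data.frame with one row per transcript: `gene_id`, `tx_name`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`,
#'   `exon_starts`, `exon_ends` (list columns).
#' @export
read_gene_models <- function(path) {
  b <- read_body_lines(path)
  fields <- strsplit(b$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 11L)
  if (length(bad))
    stop(sprintf("%s: line %d: expected 11 refFlat columns, found %d",
                 path, b$ln[bad[1]], nf[bad[1]]))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  strand <- col(4)
  badstr <- which(!strand %in% c("+", "-"))
  if (length(badstr))
    stop(sprintf("%s: line %d: unknown strand symbol '%s'", path,
                 b$ln[badstr[1]], strand[badstr[1]]))
  parse_exons <- function(s, ln, column) {
    parts <- strsplit(s, ",", fixed = TRUE)
    lapply(seq_along(parts), function(i) {
      v <- suppressWarnings(as.numeric(parts[[i]]))
      if (anyNA(v))
        stop(sprintf("%s: line %d: malformed exon list in column %s",
                     path, ln[i], column))
      v
    })
  }
  exon_starts <- parse_exons(col(10), b$ln, "exonStarts")
  exon_ends <- parse_exons(col(11), b$ln, "exonEnds")
  exon_count <- parse_coord(col(9), b$ln, path, "exonCount")
  mism <- which(lengths(exon_starts) != exon_count | lengths(exon_ends) != exon_count)
  if (length(mism))
    stop(sprintf("%s: line %d: exonCount %d does not match exon list length %d",
                 path, b$ln[mism[1]], exon_count[mism[1]],
                 lengths(exon_starts)[mism[1]]))
  out <- data.frame(
    gene_id = col(1), tx_name = col(2), chrom = col(3), strand = strand,
    tx_start = parse_coord(col(5), b$ln, path, "txStart"),
    tx_end = parse_coord(col(6), b$ln, path, "txEnd"),
    cds_start = parse_coord(col(7), b$ln, path, "cdsStart"),
    cds_end = parse_coord(col(8), b$ln, path, "cdsEnd"),
    stringsAsFactors = FALSE
  )
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  bad <- which(out$tx_start >= out$tx_end)
  if (length(bad))
    stop(sprintf("%s: line %d: txStart >= txEnd", path, b$ln[bad[1]]))
  for (i in seq_len(nrow(out))) {
    es <- out$exon_starts[[i]]; ee <- out$exon_ends[[i]]
    if (any(es >= ee) || is.unsorted(es) ||
        (length(es) > 1 && any(ee[-length(ee)] > es[-1])) ||
        es[1] < out$tx_start[i] || ee[length(ee)] > out$tx_end[i])
      stop(sprintf("%s: line %d: exons not sorted/non-overlapping within transcript",
                   path, b$ln[i]))
  }
  out
}

#' Write gene models in refFlat format
#'
#' @param genes gene-model data.frame as returned by [read_gene_models()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  fmt_list <- function(l) vapply(l, function(v)
    paste0(paste(as.integer(v), collapse = ","), ","), character(1))
  lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   genes$gene_id, genes$tx_name, genes$chrom, genes$strand,
                   as.integer(genes$tx_start), as.integer(genes$tx_end),
                   as.integer(genes$cds_start), as.integer(genes$cds_end),
                   lengths(genes$exon_starts),
                   fmt_list(genes$exon_starts), fmt_list(genes$exon_ends))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Steps are sorted per chromosome on read (shuffled input yields the same
#' track as sorted input).  Overlapping steps or non-positive spans are
#' rejected: a well-formed track is piecewise constant with implicit value 0
#' over uncovered bases.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @return a signal track: data.frame `chrom`, `start`, `end`, `value`,
#'   sorted by chromosome then start, class `"signal_track"`.
#' @export
read_bedgraph <- function(path) {
  b <- read_body_lines(path)
  if (!length(b$lines)) {
    return(as_signal_track(data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), value = numeric(),
                                      stringsAsFactors = FALSE)))
  }
  fields <- strsplit(b$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad))
    stop(sprintf("%s: line %d: expected 4 bedGraph columns, found %d",
                 path, b$ln[bad[1]], nf[bad[1]]))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- data.frame(
    chrom = col(1),
    start = parse_coord(col(2), b$ln, path, "start"),
    end = parse_coord(col(3), b$ln, path, "end"),
    value = suppressWarnings(as.numeric(col(4))),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$value))
    stop(sprintf("%s: line %d: non-numeric value", path,
                 b$ln[which(is.na(out$value))[1]]))
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop(sprintf("%s: line %d: non-positive span", path, b$ln[bad[1]]))
  as_signal_track(out, error_context = path)
}

#' Construct/validate a signal track
#'
#' Sorts steps by chromosome and start and enforces the piecewise-constant
#' track invariants (positive spans, no overlapping steps).
#'
#' @param x data.frame with `chrom`, `start`, `end`, `value`.
#' @param error_context label for error messages.
#' @return sorted, validated data.frame of class `"signal_track"`.
#' @export
as_signal_track <- function(x, error_context = "signal track") {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  if (nrow(x)) {
    if (any(x$start >= x$end)) stop(error_context, ": non-positive step span")
    x <- x[order(x$chrom, x$start), , drop = FALSE]
    rownames(x) <- NULL
    same <- x$chrom[-nrow(x)] == x$chrom[-1]
    if (nrow(x) > 1 && any(same & x$end[-nrow(x)] > x$start[-1]))
      stop(error_context, ": overlapping steps (ill-formed track)")
  }
  class(x) <- c("signal_track", class(x))
  x
}

#' Write a signal track as bedGraph
#'
#' @param track signal track.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                   as.integer(track$end), format_num(track$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a TSV with a header; column names are configurable with
#' DESeq2-style defaults.  `padj` may be missing or `NA`; duplicate gene ids
#' and non-numeric log2 fold changes are errors.
#'
#' @param path TSV file.
#' @param id_col,lfc_col,p_col,padj_col column names; set `padj_col = NULL`
#'   if the table carries no adjusted p-value.
#' @return data.frame `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
read_expression <- function(path, id_col = "gene", lfc_col = "log2FoldChange",
                            p_col = "pvalue", padj_col = "padj") {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  for (cn in c(id_col, lfc_col, p_col)) {
    if (!cn %in% names(tab))
      stop(path, ": missing required column '", cn, "'")
  }
  num <- function(cn, required) {
    raw <- tab[[cn]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) &
                   !toupper(trimws(raw)) %in% c("NA", ""))
    if (length(bad))
      stop(path, ": non-numeric value '", raw[bad[1]], "' in column '", cn, "'")
    if (required && anyNA(v))
      stop(path, ": missing value in required column '", cn, "'")
    v
  }
  out <- data.frame(
    gene_id = tab[[id_col]],
    log2fc = num(lfc_col, required = TRUE),
    pvalue = num(p_col, required = TRUE),
    stringsAsFactors = FALSE
  )
  out$padj <- if (!is.null(padj_col) && padj_col %in% names(tab))
    num(padj_col, required = FALSE) else NA_real_
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup))
    stop(path, ": duplicate gene_id '", dup[1], "'")
  if (any(out$pvalue < 0 | out$pvalue > 1, na.rm = TRUE))
    stop(path, ": p-value outside [0, 1]")
  out
}

#' Write an expression table (DESeq2-style TSV)
#'
#' @param expression data.frame from [read_expression()] or
#'   [simulate_expression()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  tab <- data.frame(gene = expression$gene_id,
                    log2FoldChange = expression$log2fc,
                    pvalue = expression$pvalue,
                    padj = expression$padj,
                    stringsAsFactors = FALSE)
  write_tsv_table(tab, path)
  invisible(path)
}

#' Write a data.frame as a TSV results table
#'
#' Tab-separated, header, no quoting or row names; list columns are collapsed
#' with commas.  The format round-trips through `read.delim`.
#'
#' @param tab data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(tab, path) {
  is_list <- vapply(tab, is.list, logical(1))
  for (cn in names(tab)[is_list])
    tab[[cn]] <- vapply(tab[[cn]], function(v) paste(v, collapse = ","), character(1))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Records package version, the echoed configuration/parameters, seed, and
#' md5 hashes of the input files, so a run can be re-executed and compared.
#' No volatile fields (timestamps) are written: two identical runs produce
#' byte-identical metadata.
#'
#' @param path output JSON file.
#' @param params named list of parameters/configuration to echo.
#' @param seed integer seed used for the run (or `NULL`).
#' @param input_files character vector of input paths to hash.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, params = list(), seed = NULL,
                               input_files = character()) {
  meta <- list(
    package = "bindexpr",
    version = as.character(utils::packageVersion("bindexpr")),
    seed = seed,
    params = params,
    input_md5 = as.list(tools::md5sum(input_files))
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
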