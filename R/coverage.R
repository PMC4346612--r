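#' Per-base coverage track
#'
#' A coverage track holds per-base read depth for one sample and assay,
#' one numeric vector per chromosome (position `i` of the vector is the
#' 0-based genomic position `i - 1`). It is the carrier for RNA-seq,
#' H3K36me3 ChIP-seq and MeDIP signal, and (with values in `[0, 1]`)
#' for mappability.
#'
#' @param cov named list of non-negative numeric vectors, one per chromosome
#' @param assay assay label, e.g. `"rnaseq"`, `"h3k36me3"`, `"medip"`
#' @param library_total total aligned reads in the library; when `NULL` it is
#'   estimated as `sum(coverage) / read_length` (wiggle-type files carry no
#'   read count)
#' @param read_length read length (bp) used for the `library_total` fallback
#' @return an object of class `coverage_track`
#' @export
coverage_track <- function(cov, assay = "rnaseq", library_total = NULL,
                           read_length = 75) {
  .chk(is.list(cov) && length(cov) > 0 && !is.null(names(cov)),
       "cov must be a named list of per-chromosome vectors")
  for (ch in names(cov)) {
    v <- cov[[ch]]
    .chk(is.numeric(v), "coverage for %s must be numeric", ch)
    if (anyNA(v) || any(v < 0))
      stop(sprintf("format error: negative or missing depth on chromosome %s", ch),
           call. = FALSE)
  }
  names(cov) <- norm_chrom(names(cov))
  estimated <- is.null(library_total)
  if (estimated) {
    library_total <- sum(vapply(cov, sum, numeric(1))) / read_length
    message(sprintf("library_total not supplied; estimated as %.0f (coverage sum / read length %d)",
                    library_total, as.integer(read_length)))
  }
  if (!estimated) {
    mx <- max(vapply(cov, function(v) if (length(v)) max(v) else 0,
                     numeric(1)))
    .chk(library_total >= mx,
         "library_total (%g) smaller than maximal single-base depth (%g)",
         library_total, mx)
  }
  structure(list(cov = cov, assay = assay, library_total = library_total,
                 library_total_estimated = estimated),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  lens <- vapply(x$cov, length, integer(1))
  cat(sprintf("coverage_track [%s]: %d chromosome(s), %g bp, library_total %g\n",
              x$assay, length(x$cov), sum(lens), x$library_total))
  invisible(x)
}

#' @export
chrom_lengths <- function(x) UseMethod("chrom_lengths")

#' @export
chrom_lengths.coverage_track <- function(x) {
  vapply(x$cov, length, numeric(1))
}

# Sums of depth over 0-based half-open intervals, vectorized by chromosome.
# `what = "breadth"` counts bases with depth >= 1 instead.
.interval_stat <- function(track, chrom, start, end, what = c("sum", "breadth")) {
  what <- match.arg(what)
  chrom <- norm_chrom(chrom)
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- track$cov[[ch]]
    if (is.null(v)) { out[i] <- 0; next }
    s <- pmin(pmax(start[i], 0), length(v))
    e <- pmin(pmax(end[i], 0), length(v))
    e <- pmax(e, s)
    cs <- if (what == "sum") c(0, cumsum(v)) else c(0, cumsum(v >= 1))
    out[i] <- cs[e + 1] - cs[s + 1]
  }
  out
}

#' Total depth over genomic intervals
#'
#' @param track a [coverage_track()]
#' @param chrom,start,end parallel vectors describing 0-based half-open
#'   intervals
#' @return numeric vector of per-interval depth sums
#' @export
interval_sums <- function(track, chrom, start, end)
  .interval_stat(track, chrom, start, end, "sum")

#' Fraction of interval bases covered by at least one read
#'
#' @inheritParams interval_sums
#' @return numeric vector of breadth values in `[0, 1]`
#' @export
interval_breadth <- function(track, chrom, start, end) {
  covered <- .interval_stat(track, chrom, start, end, "breadth")
  len <- pmax(end - start, 1)
  covered / len
}

#' Genome-wide mean per-base signal
#'
#' @param track a [coverage_track()]
#' @return scalar mean depth over all represented bases
#' @export
genome_mean_signal <- function(track) {
  tot <- sum(vapply(track$cov, sum, numeric(1)))
  len <- sum(vapply(track$cov, length, numeric(1)))
  tot / len
}

.parse_track_header <- function(line) {
  kv <- regmatches(line, gregexpr("[A-Za-z_]+=[^ \t]+", line))[[1]]
  out <- list()
  for (p in kv) {
    k <- sub("=.*", "", p)
    out[[k]] <- sub("^[^=]+=", "", p)
  }
  out
}

#' Read a coverage track from bedGraph or fixed-step wiggle
#'
#' Records must be sorted by start within each chromosome (unsorted input is
#' an error, never silently re-sorted); overlapping bedGraph records are
#' summed. `#chromlen` comment lines written by [write_coverage()] restore the
#' exact chromosome extents, making write/read round trips bit-identical.
#'
#' @param path file path (bedGraph or fixed-step WIG; gzip transparent)
#' @param assay assay label; when `NULL`, taken from the track line if present
#' @param library_total total aligned reads; when `NULL`, taken from the track
#'   line if present, else estimated from the coverage sum
#' @param read_length read length for the `library_total` fallback
#' @return a [coverage_track()]
#' @export
read_coverage <- function(path, assay = NULL, library_total = NULL,
                          read_length = 75) {
  lines <- readLines(path)
  meta <- list()
  chromlen <- list()
  body <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "track")) {
      meta <- .parse_track_header(ln)
    } else if (startsWith(ln, "#chromlen")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      chromlen[[norm_chrom(f[2])]] <- as.numeric(f[3])
    } else if (startsWith(ln, "#") || !nzchar(trimws(ln))) {
      # skip
    } else {
      body <- c(body, ln)
    }
  }
  assay <- assay %||% meta$assay %||% "rnaseq"
  if (is.null(library_total) && !is.null(meta$library_total))
    library_total <- as.numeric(meta$library_total)
  is_wig <- any(startsWith(body, "fixedStep"))
  cov <- list()
  .ensure <- function(ch, upto) {
    v <- cov[[ch]] %||% numeric(0)
    if (length(v) < upto) v <- c(v, numeric(upto - length(v)))
    cov[[ch]] <<- v
  }
  if (is_wig) {
    cur <- NULL; pos <- NA; step <- 1; span <- 1
    for (i in seq_along(body)) {
      ln <- body[i]
      if (startsWith(ln, "fixedStep")) {
        h <- .parse_track_header(ln)
        cur <- norm_chrom(h$chrom)
        start1 <- as.numeric(h$start)   # wiggle is 1-based
        step <- as.numeric(h$step %||% "1")
        span <- as.numeric(h$span %||% "1")
        .chk(!is.na(start1) && start1 >= 1, "bad fixedStep header: %s", ln)
        if (!is.na(pos) && !is.null(cov[[cur]]) && start1 < pos)
          stop(sprintf("unsorted fixedStep block on chromosome %s", cur),
               call. = FALSE)
        pos <- start1
      } else {
        val <- suppressWarnings(as.numeric(ln))
        if (is.na(val)) stop(sprintf("parse error at data line %d: '%s'", i, ln),
                             call. = FALSE)
        if (val < 0) stop("format error: negative value in wiggle", call. = FALSE)
        .ensure(cur, pos + span - 1)
        idx <- pos:(pos + span - 1)
        cov[[cur]][idx] <- cov[[cur]][idx] + val
        pos <- pos + step
      }
    }
  } else if (length(body)) {
    dt <- tryCatch(
      data.table::fread(text = body, header = FALSE, sep = "\t",
                        colClasses = list(character = 1)),
      error = function(e) stop(sprintf("parse error: %s", conditionMessage(e)),
                               call. = FALSE))
    .chk(ncol(dt) >= 4, "bedGraph needs 4 columns, found %d", ncol(dt))
    data.table::setnames(dt, 1:4, c("chrom", "start", "end", "value"))
    dt[, chrom := norm_chrom(chrom)]
    if (any(dt$value < 0))
      stop("format error: negative value in bedGraph", call. = FALSE)
    if (any(dt$end <= dt$start))
      stop("format error: empty or inverted interval in bedGraph", call. = FALSE)
    for (ch in unique(dt$chrom)) {
      d <- dt[chrom == ch]
      if (is.unsorted(d$start))
        stop(sprintf("unsorted bedGraph records on chromosome %s", ch),
             call. = FALSE)
      .ensure(ch, max(d$end))
      v <- cov[[ch]]
      # overlapping records sum: add each record's value over its range
      for (j in seq_len(nrow(d)))
        v[(d$start[j] + 1):d$end[j]] <- v[(d$start[j] + 1):d$end[j]] + d$value[j]
      cov[[ch]] <- v
    }
  }
  for (ch in names(chromlen)) .ensure(ch, chromlen[[ch]])
  for (ch in setdiff(names(chromlen), names(cov))) cov[[ch]] <- numeric(chromlen[[ch]])
  .chk(length(cov) > 0, "no coverage records in %s", path)
  suppressMessages(coverage_track(cov, assay = assay,
                                  library_total = library_total,
                                  read_length = read_length))
}

#' Write a coverage track as bedGraph or fixed-step wiggle
#'
#' Emits sorted records, a track line carrying the assay and library total,
#' and `#chromlen` comments so that [read_coverage()] reproduces the
#' per-base arrays exactly.
#'
#' @param track a [coverage_track()]
#' @param path output file path
#' @param format `"bedGraph"` or `"wig"`
#' @param use_chr_prefix prepend `"chr"` to chromosome names on output
#' @return `path`, invisibly
#' @export
write_coverage <- function(track, path, format = c("bedGraph", "wig"),
                           use_chr_prefix = FALSE) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  type <- if (format == "bedGraph") "bedGraph" else "wiggle_0"
  writeLines(sprintf("track type=%s assay=%s library_total=%.10g",
                     type, track$assay, track$library_total), con)
  for (ch in names(track$cov))
    writeLines(sprintf("#chromlen %s %d", .restore_chrom(ch, use_chr_prefix),
                       length(track$cov[[ch]])), con)
  for (ch in names(track$cov)) {
    v <- track$cov[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths        # 0-based starts
    keep <- r$values != 0
    if (!any(keep)) next
    cname <- .restore_chrom(ch, use_chr_prefix)
    if (format == "bedGraph") {
      writeLines(sprintf("%s\t%d\t%d\t%.10g", cname, starts[keep], ends[keep],
                         r$values[keep]), con)
    } else {
      for (j in which(keep)) {
        writeLines(sprintf("fixedStep chrom=%s start=%d step=1", cname,
                           starts[j] + 1L), con)
        writeLines(sprintf("%.10g", v[(starts[j] + 1L):ends[j]]), con)
      }
    }
  }
  invisible(path)
}
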