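# Genome data containers and coordinate machinery.
#
# Internal coordinates are uniformly 0-based. BED exons arrive 0-based
# half-open and are used as-is; genetic-map and call-table physical
# positions arrive 1-based (the common dialect of SNP tables) and are
# shifted by -1 at parse time. Writers undo the shift.

#' Genetic map
#'
#' Per-chromosome monotone mapping between physical position (bp) and
#' cumulative genetic position (cM).
#'
#' @param chrom chromosome identifiers (character).
#' @param pos physical positions in bp (0-based internal convention).
#' @param cM cumulative genetic positions in centimorgans.
#' @return A `data.frame` of class `genetic_map`, sorted by chromosome and
#'   position, with strictly increasing positions and non-decreasing cM
#'   within each chromosome.
#' @export
genetic_map <- function(chrom, pos, cM) {
  d <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  cM = as.numeric(cM), stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  for (ch in unique(d$chrom)) {
    i <- d$chrom == ch
    if (sum(i) < 2) stop("genetic map needs >= 2 points on chromosome ", ch)
    if (any(diff(d$pos[i]) <= 0))
      stop("genetic map positions must be strictly increasing on ", ch)
    if (any(diff(d$cM[i]) < 0))
      stop("genetic map cM must be non-decreasing on ", ch)
  }
  class(d) <- c("genetic_map", "data.frame")
  d
}

#' Exon annotation
#'
#' Exon intervals in 0-based half-open coordinates. Overlapping intervals
#' are merged per chromosome before midpoints are computed, so that each
#' merged exon is a distinct opportunity for a selected site. The selected
#' site, when present, is taken to sit at the exon midpoint
#' `floor((start + end) / 2)`.
#'
#' @param chrom chromosome identifiers.
#' @param start,end interval bounds, `end > start`, 0-based half-open.
#' @return A `data.frame` of class `exon_annotation` with columns `chrom`,
#'   `start`, `end`, `midpoint`, `length`.
#' @export
exon_annotation <- function(chrom, start, end) {
  d <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(d$end <= d$start)) stop("exon intervals must satisfy end > start")
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  d <- do.call(rbind, lapply(split(d, d$chrom), merge_intervals))
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  d$midpoint <- floor((d$start + d$end) / 2)
  d$length <- d$end - d$start
  class(d) <- c("exon_annotation", "data.frame")
  d
}

# merge strictly overlapping sorted intervals on one chromosome
merge_intervals <- function(d) {
  if (nrow(d) < 2) return(d)
  hi <- cummax(d$end)
  new_run <- c(TRUE, d$start[-1] >= hi[-nrow(d)])
  grp <- cumsum(new_run)
  data.frame(chrom = d$chrom[!duplicated(grp)],
             start = tapply(d$start, grp, min)[unique(grp)],
             end = tapply(d$end, grp, max)[unique(grp)],
             stringsAsFactors = FALSE)
}

#' Call table of observed introgressed-allele frequencies
#'
#' Per-SNP observed frequency `pn` of the introgressed allele, with
#' optional genetic positions (`gpos`, cM) attached from a [genetic_map()].
#'
#' @param chrom chromosome identifiers.
#' @param pos physical positions (0-based internal convention).
#' @param pn observed introgressed-allele frequencies in \[0, 1\].
#' @param map optional [genetic_map()]; if supplied, genetic positions are
#'   interpolated and stored in column `gpos`.
#' @return A `data.frame` of class `call_table`, sorted by chromosome and
#'   position.
#' @export
call_table <- function(chrom, pos, pn, map = NULL) {
  bad <- which(pn < 0 | pn > 1 | is.na(pn))
  if (length(bad))
    stop("frequencies outside [0, 1] at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  d <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  pn = as.numeric(pn), stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("call_table", "data.frame")
  if (!is.null(map)) d <- annotate_calls(d, map)
  d
}

#' Attach genetic positions to a call table
#'
#' @param calls a [call_table()].
#' @param map a [genetic_map()].
#' @return The call table with a `gpos` column (cM).
#' @export
annotate_calls <- function(calls, map) {
  stopifnot(inherits(calls, "call_table"), inherits(map, "genetic_map"))
  calls$gpos <- NA_real_
  for (ch in unique(calls$chrom)) {
    i <- calls$chrom == ch
    calls$gpos[i] <- interpolate_cM(map, ch, calls$pos[i])
  }
  calls
}

#' Interpolate genetic position from a map
#'
#' Piecewise-linear interpolation of cumulative cM between flanking map
#' points; queries outside the mapped range are clamped to the boundary cM
#' value (constant extrapolation).
#'
#' @param map a [genetic_map()].
#' @param chrom a single chromosome identifier present in the map.
#' @param bp physical position(s), same coordinate convention as the map.
#' @return Genetic position(s) in cM.
#' @export
interpolate_cM <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genetic_map"), length(chrom) == 1)
  i <- map$chrom == chrom
  if (!any(i)) stop("chromosome not in genetic map: ", chrom)
  stats::approx(map$pos[i], map$cM[i], xout = bp, rule = 2, ties = "ordered")$y
}

#' Genetic distance to recombination fraction
#'
#' Linear conversion `r = min(d / 100, 0.5)` (centimorgans to Morgans,
#' capped at free recombination). No map function is applied: at the
#' window scales used here (<= 10 cM) Haldane/Kosambi corrections are
#' negligible. For the X chromosome the 2/3 male/female time-weighting is
#' applied inside [f_xchr()], not here.
#'
#' @param d genetic distance(s) in cM, non-negative.
#' @return Recombination fraction(s) in \[0, 0.5\].
#' @export
recomb_fraction <- function(d) {
  if (any(d < 0)) stop("genetic distance must be non-negative")
  pmin(d / 100, 0.5)
}

#' Linked-exon window around a focal site
#'
#' Collects the exons whose midpoints lie within `window_cM / 2` of the
#' focal site's genetic position, ordered by increasing genetic distance
#' (ties broken toward the lower physical coordinate), and converts the
#' distances to recombination fractions.
#'
#' @param exons an [exon_annotation()].
#' @param map a [genetic_map()].
#' @param chrom chromosome of the focal site.
#' @param pos physical position of the focal site.
#' @param window_cM full window size in cM (default 1; 10 supported).
#' @return A [linked_exon_context()] (possibly empty).
#' @export
build_window <- function(exons, map, chrom, pos, window_cM = 1) {
  stopifnot(inherits(exons, "exon_annotation"), window_cM > 0)
  g0 <- interpolate_cM(map, chrom, pos)
  i <- which(exons$chrom == chrom)
  if (!length(i)) return(linked_exon_context())
  gmid <- interpolate_cM(map, chrom, exons$midpoint[i])
  d <- abs(gmid - g0)
  keep <- d <= window_cM / 2
  if (!any(keep)) return(linked_exon_context())
  i <- i[keep]; d <- d[keep]
  o <- order(d, exons$start[i])
  structure(list(r = recomb_fraction(d[o]), lengths = exons$length[i][o]),
            class = "linked_exon_context")
}

# ---- readers / writers ------------------------------------------------

read_delim_checked <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#"),
    error = function(e) stop("failed to parse ", what, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
}

has_header <- function(d) !is.na(d[[2]][1]) && is.na(suppressWarnings(as.numeric(d[[2]][1])))

#' Read a genetic map file
#'
#' Whitespace- or tab-delimited columns: chromosome, physical position
#' (bp, 1-based), cumulative cM. A header line is detected automatically;
#' gzip-compressed files are read transparently.
#'
#' @param path file path.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  d <- read_delim_checked(path, "genetic map")
  if (ncol(d) < 3) stop("genetic map needs 3 columns (chrom, pos, cM)")
  if (has_header(d)) d <- d[-1, , drop = FALSE]
  pos <- suppressWarnings(as.numeric(d[[2]]))
  cM <- suppressWarnings(as.numeric(d[[3]]))
  bad <- which(is.na(pos) | is.na(cM))
  if (length(bad))
    stop("malformed genetic map line ", bad[1], " in ", path)
  genetic_map(d[[1]], pos - 1, cM)
}

#' Read an exon annotation (BED)
#'
#' BED with at least 3 columns, 0-based half-open; `track`/`browser`/`#`
#' lines are skipped and overlapping intervals are merged.
#'
#' @param path file path.
#' @return An [exon_annotation()].
#' @export
read_exons <- function(path) {
  if (!file.exists(path)) stop("exon BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) stop("no intervals in BED file: ", path)
  d <- tryCatch(
    read.table(text = lines, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(d) < 3) stop("BED file needs >= 3 columns")
  st <- suppressWarnings(as.numeric(d[[2]]))
  en <- suppressWarnings(as.numeric(d[[3]]))
  bad <- which(is.na(st) | is.na(en))
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  exon_annotation(d[[1]], st, en)
}

#' Read a call table
#'
#' Tab-delimited columns: chromosome, physical position (1-based),
#' observed introgressed-allele frequency in \[0, 1\]; optional header,
#' gzip transparent.
#'
#' @param path file path.
#' @param map optional [genetic_map()] used to attach genetic positions.
#' @return A [call_table()].
#' @export
read_calls <- function(path, map = NULL) {
  d <- read_delim_checked(path, "call table")
  if (ncol(d) < 3) stop("call table needs 3 columns (chrom, pos, pn)")
  if (has_header(d)) d <- d[-1, , drop = FALSE]
  pos <- suppressWarnings(as.numeric(d[[2]]))
  pn <- suppressWarnings(as.numeric(d[[3]]))
  bad <- which(is.na(pos) | is.na(pn))
  if (length(bad)) stop("malformed call-table line ", bad[1], " in ", path)
  out <- which(pn < 0 | pn > 1)
  if (length(out))
    stop("frequency outside [0, 1] at line ", out[1], " in ", path)
  call_table(d[[1]], pos - 1, pn, map = map)
}

#' Write genome data files
#'
#' Writers matching the [read_genetic_map()], [read_exons()] and
#' [read_calls()] dialects (map and call positions written 1-based, BED
#' 0-based half-open). Round-tripping reproduces identical objects.
#'
#' @param x object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(x, path) {
  stopifnot(inherits(x, "genetic_map"))
  write.table(data.frame(x$chrom, x$pos + 1, x$cM), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
write_exons <- function(x, path) {
  stopifnot(inherits(x, "exon_annotation"))
  write.table(data.frame(x$chrom, x$start, x$end), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
write_calls <- function(x, path) {
  stopifnot(inherits(x, "call_table"))
  write.table(data.frame(chrom = x$chrom, pos = x$pos + 1, pn = x$pn), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
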