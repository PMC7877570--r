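#' Marker grid with physical and genetic coordinates
#'
#' A genomic map binds a set of marker positions (1-based basepairs) to
#' genetic positions (centimorgans) per chromosome. Positions must be strictly
#' increasing and genetic positions non-decreasing within a chromosome.
#' Chromosome lengths (bp) are carried so that tract simulation and
#' interpolation can cover the full chromosome, not just the marker span.
#'
#' @param chrom character vector of chromosome labels, one per marker.
#' @param pos integer vector of 1-based marker positions (bp).
#' @param cm numeric vector of genetic positions (cM); if `NULL`, a constant
#'   rate of `rate_cm_per_mb` cM/Mb is assumed.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   defaults to the last marker position per chromosome.
#' @param rate_cm_per_mb constant recombination rate used when `cm` is `NULL`
#'   and to extrapolate beyond the marker span.
#' @return A tibble of class `genomic_map` with columns `chrom`, `pos`, `cm`.
#' @export
genomic_map <- function(chrom, pos, cm = NULL, chrom_lengths = NULL,
                        rate_cm_per_mb = 1) {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (is.null(cm)) cm <- pos * 1e-6 * rate_cm_per_mb
  if (length(chrom) != length(pos) || length(pos) != length(cm)) {
    stop("chrom, pos and cm must have equal length", call. = FALSE)
  }
  m <- tibble::tibble(chrom = chrom, pos = pos, cm = as.numeric(cm))
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    if (any(diff(m$pos[i]) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch, call. = FALSE)
    }
    if (any(diff(m$cm[i]) < 0)) {
      stop("genetic positions decreasing on chromosome ", ch, call. = FALSE)
    }
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(m$pos, m$chrom), max, numeric(1))
  }
  if (is.null(names(chrom_lengths)) && length(chrom_lengths) == length(unique(m$chrom))) {
    names(chrom_lengths) <- unique(m$chrom)
  }
  if (!all(unique(m$chrom) %in% names(chrom_lengths))) {
    stop("chrom_lengths must name every chromosome in the map", call. = FALSE)
  }
  structure(m,
    chrom_lengths = chrom_lengths[unique(m$chrom)],
    rate_cm_per_mb = rate_cm_per_mb,
    class = c("genomic_map", class(m))
  )
}

#' Evenly spaced constant-rate map
#'
#' Convenience constructor for a marker grid with equal spacing and a constant
#' recombination rate (default 1 cM/Mb), the usual desk-scale stand-in when no
#' population-specific recombination map is available.
#'
#' @param chrom_lengths named numeric vector, chromosome lengths in bp.
#' @param markers_per_chrom number of markers placed on each chromosome.
#' @param rate_cm_per_mb recombination rate in cM/Mb.
#' @return A `genomic_map`.
#' @export
constant_rate_map <- function(chrom_lengths, markers_per_chrom,
                              rate_cm_per_mb = 1) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  }
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome", call. = FALSE)
  pos <- unlist(lapply(chrom_lengths, function(L) {
    round(seq(1, L, length.out = markers_per_chrom))
  }), use.names = FALSE)
  chrom <- rep(names(chrom_lengths), each = markers_per_chrom)
  genomic_map(chrom, pos,
    chrom_lengths = chrom_lengths,
    rate_cm_per_mb = rate_cm_per_mb
  )
}

map_chrom_lengths <- function(map) attr(map, "chrom_lengths")

#' Total genetic length of a map in Morgans
#' @param map a `genomic_map`.
#' @return total genetic length across chromosomes, in Morgans.
#' @export
map_morgans <- function(map) {
  sum(vapply(unique(map$chrom), function(ch) {
    bp_to_cm(map, ch, map_chrom_lengths(map)[[ch]])
  }, numeric(1))) / 100
}

# anchor table covering [0, L] for one chromosome; extrapolates the marker
# grid to the chromosome ends with the boundary segment rate
.map_anchors <- function(map, chrom) {
  i <- map$chrom == chrom
  if (!any(i)) stop("chromosome ", chrom, " not in map", call. = FALSE)
  pos <- map$pos[i]
  cm <- map$cm[i]
  L <- map_chrom_lengths(map)[[chrom]]
  rate <- attr(map, "rate_cm_per_mb")
  tail_rate <- if (length(pos) > 1) {
    (cm[length(cm)] - cm[1]) / (pos[length(pos)] - pos[1]) # mean cM/bp
  } else rate * 1e-6
  p0 <- c(0, pos)
  c0 <- c(max(0, cm[1] - pos[1] * tail_rate), cm)
  if (L > pos[length(pos)]) {
    p0 <- c(p0, L)
    c0 <- c(c0, cm[length(cm)] + (L - pos[length(pos)]) * tail_rate)
  }
  list(pos = p0, cm = c0)
}

bp_to_cm <- function(map, chrom, bp) {
  a <- .map_anchors(map, chrom)
  stats::approx(a$pos, a$cm, xout = bp, rule = 2)$y
}

cm_to_bp <- function(map, chrom, cm) {
  a <- .map_anchors(map, chrom)
  stats::approx(a$cm, a$pos, xout = cm, rule = 2, ties = "ordered")$y
}

#' Read / write a genomic map as TSV
#'
#' The file has columns `chrom`, `pos`, `cm` and a header comment carrying
#' the chromosome lengths (`#lengths: 1=50000000 2=50000000`).
#'
#' @param path file path.
#' @return [read_genomic_map()] returns a [genomic_map()];
#'   `write_genomic_map` returns `path` invisibly.
#' @export
read_genomic_map <- function(path) {
  first <- readLines(path, n = 1L)
  lens <- NULL
  if (grepl("^#lengths:", first)) {
    kv <- strsplit(trimws(sub("^#lengths:", "", first)), "[ \t]+")[[1]]
    parts <- strsplit(kv, "=")
    lens <- stats::setNames(
      as.numeric(vapply(parts, `[`, character(1), 2)),
      vapply(parts, `[`, character(1), 1)
    )
  }
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(chrom = readr::col_character()))
  genomic_map(d$chrom, d$pos, d$cm, chrom_lengths = lens)
}

#' @param map a [genomic_map()].
#' @rdname read_genomic_map
#' @export
write_genomic_map <- function(map, path) {
  lens <- map_chrom_lengths(map)
  cat(paste0("#lengths: ",
             paste(sprintf("%s=%.0f", names(lens), lens), collapse = " "),
             "\n"), file = path)
  cat(readr::format_tsv(tibble::as_tibble(map)), file = path, append = TRUE)
  invisible(path)
}
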