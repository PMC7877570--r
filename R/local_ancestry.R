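#' Per-haplotype local ancestry tracts
#'
#' A `local_ancestry_set` holds, for every haplotype of every individual, the
#' tiling of each chromosome into ancestry tracts, together with the tract
#' posterior probability reported by the upstream local-ancestry caller.
#' Coordinates are 1-based closed intervals `[spos, epos]`; the tracts of one
#' haplotype must tile each chromosome without overlap or gap.
#'
#' @param tracts tibble with columns `individual`, `haplotype` (1 or 2),
#'   `chrom`, `spos`, `epos`, `ancestry`, `posterior`.
#' @param map a [genomic_map()] giving the marker grid and chromosome lengths.
#' @param ancestries character vector of valid ancestry codes, in reporting
#'   order (default `c("PNS","EUR","EAS","AFR")`).
#' @return object of class `local_ancestry_set`.
#' @export
local_ancestry_set <- function(tracts, map,
                               ancestries = c("PNS", "EUR", "EAS", "AFR")) {
  need <- c("individual", "haplotype", "chrom", "spos", "epos", "ancestry")
  if (!all(need %in% names(tracts))) {
    stop("tracts must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"posterior" %in% names(tracts)) tracts$posterior <- 1.0
  tracts <- tibble::as_tibble(tracts)
  tracts$individual <- as.character(tracts$individual)
  tracts$chrom <- as.character(tracts$chrom)
  bad <- setdiff(unique(tracts$ancestry), ancestries)
  if (length(bad)) {
    stop("unknown ancestry code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tracts$posterior < 0 | tracts$posterior > 1)) {
    stop("tract posterior outside [0,1]", call. = FALSE)
  }
  tracts <- dplyr::arrange(tracts, .data$individual, .data$haplotype,
                           .data$chrom, .data$spos)
  .check_tiling(tracts, map)
  structure(
    list(
      tracts = tracts,
      map = map,
      individuals = unique(tracts$individual),
      ancestries = ancestries
    ),
    class = "local_ancestry_set"
  )
}

.check_tiling <- function(tracts, map) {
  lens <- map_chrom_lengths(map)
  grp <- split(
    tracts,
    list(tracts$individual, tracts$haplotype, tracts$chrom),
    drop = TRUE
  )
  for (g in grp) {
    key <- sprintf(
      "individual %s haplotype %d chromosome %s",
      g$individual[1], g$haplotype[1], g$chrom[1]
    )
    L <- lens[[g$chrom[1]]]
    if (is.null(L)) stop("chromosome ", g$chrom[1], " not in map", call. = FALSE)
    if (any(g$epos < g$spos)) stop("tract with epos < spos on ", key, call. = FALSE)
    if (g$spos[1] != 1) {
      stop("tracts do not start at 1 on ", key,
           " (first tract [", g$spos[1], ",", g$epos[1], "])", call. = FALSE)
    }
    if (g$epos[nrow(g)] != L) {
      stop("tracts do not reach chromosome end (", L, ") on ", key, call. = FALSE)
    }
    if (nrow(g) > 1) {
      gap <- g$spos[-1] - g$epos[-nrow(g)] - 1
      if (any(gap != 0)) {
        j <- which(gap != 0)[1]
        what <- if (gap[j] > 0) "gap" else "overlap"
        stop(sprintf(
          "%s between tracts [%d,%d] and [%d,%d] on %s",
          what, g$spos[j], g$epos[j], g$spos[j + 1], g$epos[j + 1], key
        ), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.local_ancestry_set <- function(x, ...) {
  cat(
    "<local_ancestry_set> ", length(x$individuals), " individuals, ",
    nrow(x$tracts), " tracts, ancestries ",
    paste(x$ancestries, collapse = "/"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read local-ancestry tracts from a tab-separated file
#'
#' The file carries one tract per row with columns `individual`, `haplotype`,
#' `chm`, `spos`, `epos`, `ancestry` and optionally `posterior` (assumed 1.0
#' when absent), preceded by a header comment naming the ancestry codes
#' (`#codes: PNS EUR EAS AFR`). Tract tiling is validated on read; a gapped or
#' overlapping haplotype is a format error naming the haplotype and interval.
#'
#' @param path file path.
#' @param map a [genomic_map()]; if `NULL` a constant 1 cM/Mb map over the
#'   observed tract span is constructed (one marker per tract boundary).
#' @return a [local_ancestry_set()].
#' @export
read_local_ancestry <- function(path, map = NULL) {
  first <- readLines(path, n = 1L)
  ancestries <- c("PNS", "EUR", "EAS", "AFR")
  if (grepl("^#codes:", first)) {
    ancestries <- strsplit(trimws(sub("^#codes:", "", first)), "[ \t]+")[[1]]
  }
  tr <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      individual = readr::col_character(),
      chm = readr::col_character()
    )
  )
  names(tr)[names(tr) == "chm"] <- "chrom"
  if (is.null(map)) {
    lens <- vapply(split(tr$epos, tr$chrom), max, numeric(1))
    map <- constant_rate_map(lens, markers_per_chrom = 2L)
  }
  local_ancestry_set(tr, map, ancestries = ancestries)
}

#' Write local-ancestry tracts to a tab-separated file
#'
#' Inverse of [read_local_ancestry()]; the pair is a lossless round trip.
#'
#' @param la a [local_ancestry_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_local_ancestry <- function(la, path) {
  tr <- la$tracts
  names(tr)[names(tr) == "chrom"] <- "chm"
  cat(paste0("#codes: ", paste(la$ancestries, collapse = " "), "\n"),
      file = path)
  cat(readr::format_tsv(tr), file = path, append = TRUE)
  invisible(path)
}
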