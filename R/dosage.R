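#' Variant dosage matrix
#'
#' Holds expected allele dosages in `[0, 2]` (individuals x variants) together
#' with per-variant metadata: coordinates, REF/ALT alleles, and an imputation
#' INFO score in `[0, 1]`. Throughout the package the ALT allele is taken to
#' be the derived allele, so `daf` (derived allele frequency) is the mean
#' dosage divided by two.
#'
#' @param variants tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `info` (`id`, `ref`, `alt`, `info` optional; INFO defaults to 1.0).
#' @param dosage numeric matrix, individuals in rows, variants in columns.
#' @param individuals character vector of individual ids (defaults to the
#'   dosage rownames).
#' @return object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(variants, dosage, individuals = rownames(dosage)) {
  variants <- tibble::as_tibble(variants)
  if (!all(c("chrom", "pos") %in% names(variants))) {
    stop("variants need chrom and pos columns", call. = FALSE)
  }
  variants$chrom <- as.character(variants$chrom)
  if (!"id" %in% names(variants)) {
    variants$id <- paste0(variants$chrom, ":", variants$pos)
  }
  if (!"ref" %in% names(variants)) variants$ref <- "A"
  if (!"alt" %in% names(variants)) variants$alt <- "T"
  if (!"info" %in% names(variants)) variants$info <- 1.0
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage columns must match variant rows", call. = FALSE)
  }
  bad <- which(dosage < 0 | dosage > 2, arr.ind = TRUE)
  if (nrow(bad)) {
    v <- variants[bad[1, 2], ]
    stop(sprintf(
      "dosage %.3f outside [0,2] at %s:%d (individual %s)",
      dosage[bad[1, , drop = FALSE]], v$chrom, v$pos,
      if (is.null(individuals)) bad[1, 1] else individuals[bad[1, 1]]
    ), call. = FALSE)
  }
  for (ch in unique(variants$chrom)) {
    if (is.unsorted(variants$pos[variants$chrom == ch])) {
      stop("variant positions unsorted on chromosome ", ch, call. = FALSE)
    }
  }
  if (is.null(individuals)) individuals <- as.character(seq_len(nrow(dosage)))
  dimnames(dosage) <- list(individuals, variants$id)
  structure(list(variants = variants, dosage = dosage, individuals = individuals),
    class = "dosage_matrix"
  )
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(
    "<dosage_matrix> ", length(x$individuals), " individuals x ",
    nrow(x$variants), " variants\n",
    sep = ""
  )
  invisible(x)
}

#' Derived (ALT) allele frequency per variant
#' @param dm a [dosage_matrix()].
#' @return numeric vector of frequencies in `[0,1]`.
#' @export
derived_allele_freq <- function(dm) {
  colMeans(dm$dosage, na.rm = TRUE) / 2
}

#' Read dosages from a VCF or a dosage TSV
#'
#' VCF input (via the vcfR parser) uses the `DS` FORMAT field when present and
#' otherwise converts hard `GT` calls to ALT-allele counts. The `INFO=` key
#' `INFO` (imputation quality) is attached per variant when present, defaulting
#' to 1.0. Indels are skipped with a logged count. TSV input expects columns
#' `chrom`, `pos`, `id`, `ref`, `alt`, `info` followed by one dosage column per
#' individual; TSV and VCF encodings of the same matrix load identically.
#'
#' @param path path to a `.vcf` (uncompressed or gzipped) or a `.tsv` file.
#' @return a [dosage_matrix()].
#' @export
read_dosages <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) .read_dosages_vcf(path) else .read_dosages_tsv(path)
}

.read_dosages_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = readr::col_character()))
  meta_cols <- c("chrom", "pos", "id", "ref", "alt", "info")
  ind <- setdiff(names(d), meta_cols)
  dosage <- t(as.matrix(d[, ind]))
  rownames(dosage) <- ind
  dosage_matrix(d[, intersect(meta_cols, names(d))], dosage, individuals = ind)
}

.read_dosages_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_indel <- nchar(fix$REF) != 1 | nchar(fix$ALT) != 1 | grepl(",", fix$ALT)
  if (any(is_indel)) {
    message(sum(is_indel), " indel/multiallelic record(s) skipped")
  }
  keep <- !is_indel
  info <- rep(1.0, nrow(fix))
  got <- grepl("INFO=", fix$INFO)
  hits <- regmatches(fix$INFO, regexpr("INFO=[0-9.eE+-]+", fix$INFO))
  info[got] <- as.numeric(sub("INFO=", "", hits))
  ds <- tryCatch(
    vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
    error = function(e) NULL
  )
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(gsub("\\|", "/", col), "/"), function(a) {
        sum(as.numeric(a)) }, numeric(1))
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(fix))
  }
  dosage <- t(ds[keep, , drop = FALSE])
  variants <- tibble::tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
      paste0(fix$CHROM[keep], ":", fix$POS[keep]), fix$ID[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep], info = info[keep]
  )
  rownames(dosage) <- colnames(v@gt)[-1]
  dosage_matrix(variants, dosage)
}

#' Write a dosage matrix as TSV
#' @param dm a [dosage_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(dm, path) {
  out <- dplyr::bind_cols(
    dm$variants[, c("chrom", "pos", "id", "ref", "alt", "info")],
    tibble::as_tibble(t(dm$dosage), .name_repair = "minimal")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a dosage matrix as a minimal VCF with DS genotypes
#'
#' Emits an uncompressed VCFv4.2 text file with the per-variant INFO score in
#' the `INFO=` key and dosages in the `DS` FORMAT field (plus a hard `GT`
#' rounded from the dosage, for tools that require it).
#'
#' @param dm a [dosage_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected ALT dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dm$individuals), collapse = "\t")
  ), con)
  v <- dm$variants
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1]
  lines <- vapply(seq_len(nrow(v)), function(j) {
    d <- dm$dosage[, j]
    paste(c(
      v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
      sprintf("INFO=%g", v$info[j]), "GT:DS",
      paste0(gt_of(d), ":", format(d, trim = TRUE, digits = 10))
    ), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}
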