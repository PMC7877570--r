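#' Phenotype and covariate table
#'
#' A tibble of one row per individual carrying trait values, covariates and
#' the census-tract cluster label, with trait metadata (type and any
#' transformation applied) stored as an attribute. Binary traits are coded
#' 0/1; education is ordinal 1-4; nSES is a quintile 1-5.
#'
#' @param data tibble with an `id` column plus trait and covariate columns.
#' @param traits named character vector mapping trait column names to their
#'   type, `"quantitative"` or `"binary"`.
#' @return object of class `cohort_table` (a tibble).
#' @export
cohort_table <- function(data, traits) {
  data <- tibble::as_tibble(data)
  if (!"id" %in% names(data)) stop("cohort needs an id column", call. = FALSE)
  miss <- setdiff(names(traits), names(data))
  if (length(miss)) stop("trait column(s) missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  for (tr in names(traits)) {
    if (traits[[tr]] == "binary") {
      v <- data[[tr]]
      if (!all(v %in% c(0, 1, NA))) {
        stop("binary trait ", tr, " must be coded 0/1", call. = FALSE)
      }
    }
  }
  if ("education" %in% names(data) &&
      !all(data$education %in% c(1:4, NA))) {
    stop("education levels must be in 1..4", call. = FALSE)
  }
  if ("nses" %in% names(data) && !all(data$nses %in% c(1:5, NA))) {
    stop("nSES must be a quintile in 1..5", call. = FALSE)
  }
  structure(data, traits = traits,
            class = c("cohort_table", class(data)))
}

#' @export
print.cohort_table <- function(x, ...) {
  tr <- attr(x, "traits")
  cat("<cohort_table> ", nrow(x), " individuals; traits: ",
      paste(sprintf("%s (%s)", names(tr), unname(tr)), collapse = ", "),
      "\n", sep = "")
  NextMethod()
}

#' Trait metadata of a cohort table
#' @param cohort a [cohort_table()].
#' @return named character vector of trait types.
#' @export
trait_types <- function(cohort) attr(cohort, "traits")

#' Read a phenotype CSV written by [write_phenotypes()]
#'
#' Trait typing is recovered from a `#traits:` header comment
#' (`name=quantitative|binary` pairs); without it, 0/1-valued columns other
#' than known covariates are treated as binary traits.
#'
#' @param path file path.
#' @return a [cohort_table()].
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  traits <- NULL
  if (grepl("^#traits:", first)) {
    kv <- strsplit(trimws(sub("^#traits:", "", first)), "[ ,]+")[[1]]
    parts <- strsplit(kv, "=")
    traits <- stats::setNames(
      vapply(parts, `[`, character(1), 2),
      vapply(parts, `[`, character(1), 1)
    )
  }
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(id = readr::col_character()))
  if (is.null(traits)) {
    covs <- c("id", "age", "sex", "education", "smoking", "nses",
              "census_tract")
    cand <- setdiff(names(d), covs)
    type <- vapply(cand, function(nm) {
      if (all(d[[nm]] %in% c(0, 1, NA))) "binary" else "quantitative"
    }, character(1))
    traits <- type
  }
  cohort_table(d, traits)
}

#' Write a cohort table as CSV
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  tr <- trait_types(cohort)
  cat(paste0("#traits: ",
             paste(sprintf("%s=%s", names(tr), unname(tr)), collapse = " "),
             "\n"), file = path)
  cat(readr::format_csv(tibble::as_tibble(cohort)), file = path, append = TRUE)
  invisible(path)
}
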