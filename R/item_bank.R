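#' Read a 2PL item parameter bank from CSV
#'
#' Expects columns `item_id`, `alpha` (discrimination) and `beta`
#' (difficulty, logit scale); `se_alpha`, `se_beta` and `validity_r` are
#' optional metadata. Unicode minus signs in numeric columns are normalized
#' on ingest. Validation fails with row context on duplicate ids,
#' non-positive discriminations, or missing values.
#'
#' @param path path to a CSV file.
#' @return an `item_bank`: a validated data frame with one row per item.
#' @seealso [ncsr_bank()] for the bank shipped with the package.
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) stop("item bank file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (nrow(df) == 0L) stop("item bank file is empty: ", path)
  required <- c("item_id", "alpha", "beta")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("item bank is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  numify <- function(x) as.numeric(gsub("[−–—]", "-", x))
  for (col in intersect(c("alpha", "se_alpha", "beta", "se_beta",
                          "validity_r"), names(df))) {
    df[[col]] <- numify(df[[col]])
  }
  item_bank(df)
}

#' Construct and validate an item bank
#'
#' @param df data frame with at least `item_id`, `alpha`, `beta`.
#' @return the validated data frame with class `item_bank` prepended.
#' @export
item_bank <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("item_id", "alpha", "beta") %in% names(df)))
  df$item_id <- as.character(df$item_id)
  dup <- df$item_id[duplicated(df$item_id)]
  if (length(dup)) {
    stop("duplicate item id(s) in bank: ", paste(unique(dup), collapse = ", "))
  }
  bad <- which(!is.finite(df$alpha) | df$alpha <= 0)
  if (length(bad)) {
    stop("non-positive or missing discrimination at row(s) ",
         paste(bad, collapse = ", "), " (item ",
         paste(df$item_id[bad], collapse = ", "), ")")
  }
  bad_b <- which(!is.finite(df$beta))
  if (length(bad_b)) {
    stop("missing difficulty at row(s) ", paste(bad_b, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("item_bank", "data.frame")
  df
}

#' The 21-item NCS-R PTSD screening bank
#'
#' Fixed 2PL parameters of the 21 dichotomous DSM-IV PTSD symptom items of
#' the National Comorbidity Survey Replication screening section, calibrated
#' by marginal maximum likelihood on n = 880 respondents, together with
#' their standard errors and per-item criterion validity correlations.
#' These parameters are consumed as known constants throughout the package;
#' no item calibration is performed.
#'
#' @return an `item_bank` with 21 rows and columns `item_id`, `alpha`,
#'   `se_alpha`, `beta`, `se_beta`, `validity_r`.
#' @export
ncsr_bank <- function() {
  read_item_bank(system.file("extdata", "ncsr_bank.csv",
                             package = "textprior"))
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d items, discrimination [%.2f, %.2f], difficulty [%.2f, %.2f]\n",
              nrow(x), min(x$alpha), max(x$alpha), min(x$beta), max(x$beta)))
  print.data.frame(x, ...)
  invisible(x)
}
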