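#' The 50-item AQ scoring key
#'
#' Item-to-subscale assignment and scored direction for the Autism-Spectrum
#' Quotient, following the original questionnaire's standard scoring: an
#' item contributes 1 point when the response falls on its keyed side
#' (agree for `agree_scored` items, disagree otherwise), collapsing
#' "slightly" and "strongly". Five subscales of 10 items each: social
#' skills, attention switching, attention to detail, communication,
#' imagination. Shipped as a versioned data file.
#'
#' @return Tibble with `item` (1-50), `subscale`, `agree_scored` (logical).
#' @export
aq_key <- function() {
  path <- system.file("extdata", "aq_key.csv", package = "pupilstyle",
                      mustWork = TRUE)
  key <- readr::read_csv(path, col_types = readr::cols(
    item = readr::col_integer(), subscale = readr::col_character(),
    agree_scored = readr::col_logical()))
  stopifnot(nrow(key) == 50, all(table(key$subscale) == 10))
  key
}

aq_subscales <- c("social_skills", "attention_switching",
                  "attention_to_detail", "communication", "imagination")

#' Score AQ questionnaire responses
#'
#' Responses are coded 1-4 (1 = strongly agree, 2 = slightly agree,
#' 3 = slightly disagree, 4 = strongly disagree). An item scores 1 when the
#' response direction (agree vs disagree, collapsing slight/strong) matches
#' the keyed direction. Missing or out-of-range codes are an error naming
#' the item.
#'
#' @param responses Tibble with `subject` and `item_01`..`item_50`.
#' @param key AQ key (see [aq_key()]).
#' @param clinical_threshold Total at or above which a clinical assessment
#'   is conventionally recommended (32).
#' @return Tibble with `subject`, `total`, one column per subscale, and
#'   `clinical_flag` (`total >= clinical_threshold`).
#' @export
score_aq <- function(responses, key = aq_key(), clinical_threshold = 32) {
  item_cols <- sprintf("item_%02d", 1:50)
  missing_cols <- setdiff(item_cols, names(responses))
  if (length(missing_cols) > 0) {
    stop("missing item columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(responses[item_cols])
  bad <- which(!(mat %in% 1:4) | is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid/missing response for subject row %d, %s",
                 bad[1, 1], item_cols[bad[1, 2]]), call. = FALSE)
  }
  agree <- mat <= 2
  scored <- sweep(agree, 2, key$agree_scored, "==") * 1L
  out <- tibble::tibble(subject = responses$subject)
  for (sc in aq_subscales) {
    out[[sc]] <- as.integer(rowSums(scored[, key$subscale == sc,
                                           drop = FALSE]))
  }
  out$total <- as.integer(rowSums(scored))
  out$clinical_flag <- out$total >= clinical_threshold
  out[, c("subject", "total", aq_subscales, "clinical_flag")]
}

#' Corrected totals: sum of the other four subscales
#'
#' For each subscale, the sum of the remaining four (i.e. total minus the
#' subscale itself), per subject. Used when correlating a subscale against
#' the rest of the questionnaire.
#'
#' @param subscales Matrix or data frame with exactly 5 subscale columns
#'   (one row per subject).
#' @return Matrix of the same shape: column j is total - subscale j.
#' @export
corrected_totals <- function(subscales) {
  m <- as.matrix(subscales)
  if (ncol(m) != 5) stop("expected exactly 5 subscale columns", call. = FALSE)
  total <- rowSums(m)
  out <- total - m
  dimnames(out) <- dimnames(m)
  out
}

#' Jarque-Bera test of composite normality
#'
#' `JB = n/6 (S^2 + K^2/4)` with sample skewness `S` and excess kurtosis
#' `K` computed from central moments. The p-value uses the chi-square(2)
#' asymptotic by default; the Monte-Carlo mode simulates the null
#' distribution of JB at the observed `n` (the asymptotic is anticonservative
#' at small samples).
#'
#' @param x Numeric vector, `n >= 8`.
#' @param method `"asymptotic"` or `"monte_carlo"`.
#' @param n_rep Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo null.
#' @return List with `statistic`, `p_value`, `skewness`, `kurtosis_excess`,
#'   `method`.
#' @export
check_normality <- function(x, method = c("asymptotic", "monte_carlo"),
                            n_rep = 10000, seed = 1L) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  jb_stat <- function(x) {
    n <- length(x)
    m <- mean(x)
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    S <- m3 / m2^1.5
    K <- m4 / m2^2 - 3
    c(jb = n / 6 * (S^2 + K^2 / 4), S = S, K = K)
  }
  obs <- jb_stat(x)
  p <- if (method == "asymptotic") {
    stats::pchisq(obs[["jb"]], df = 2, lower.tail = FALSE)
  } else {
    withr::with_seed(seed, {
      null <- replicate(n_rep, jb_stat(stats::rnorm(n))[["jb"]])
      (sum(null >= obs[["jb"]]) + 1) / (n_rep + 1)
    })
  }
  list(statistic = obs[["jb"]], p_value = p, skewness = obs[["S"]],
       kurtosis_excess = obs[["K"]], method = method)
}
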