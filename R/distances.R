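#' String distances used for within-cluster feature extraction
#'
#' `levenshtein()` is the standard unit-cost edit distance (insertions,
#' deletions, substitutions), computed with [utils::adist()]. It is applied to
#' zero-padded date-of-birth components ("02" vs "24") and single-character
#' sex codes, where it reduces to a small integer count of differing
#' characters.
#'
#' `jaro_winkler()` returns the Jaro-Winkler *similarity* in \[0, 1\]
#' (prefix scale 0.1, maximum rewarded prefix 4 characters, prefix bonus
#' applied only when the Jaro similarity exceeds 0.7, as in the reference
#' definition). `jw_distance()` returns `1 - jaro_winkler()`, the
#' dissimilarity orientation used by the collision features: larger values
#' mean more different names or numbers.
#'
#' @param a,b character vectors, recycled to a common length. `NA` in either
#'   position yields `NA` in the result.
#' @param prefix_scale Winkler prefix scaling factor.
#' @param max_prefix maximum prefix length rewarded.
#' @param boost_threshold Jaro similarity above which the prefix bonus
#'   applies.
#' @return `levenshtein()`: integer vector. `jaro_winkler()`,
#'   `jw_distance()`: numeric vector in \[0, 1\].
#' @examples
#' levenshtein("1969", "2007") # 4
#' jw_distance("JOHN", "CHRIS")
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- rep(NA_integer_, n)
  ok <- !is.na(a) & !is.na(b)
  for (i in which(ok)) out[i] <- as.integer(utils::adist(a[i], b[i]))
  out
}

# Jaro similarity of two non-NA scalar strings.
.jaro_sim <- function(a, b) {
  s1 <- strsplit(a, "", fixed = TRUE)[[1L]]
  s2 <- strsplit(b, "", fixed = TRUE)[[1L]]
  n1 <- length(s1)
  n2 <- length(s2)
  if (n1 == 0L && n2 == 0L) return(1)
  if (n1 == 0L || n2 == 0L) return(0)
  window <- max(floor(max(n1, n2) / 2) - 1L, 0L)
  used2 <- logical(n2)
  match1 <- logical(n1)
  for (i in seq_len(n1)) {
    lo <- max(1L, i - window)
    hi <- min(n2, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!used2[j] && s1[i] == s2[j]) {
        match1[i] <- TRUE
        used2[j] <- TRUE
        break
      }
    }
  }
  m <- sum(match1)
  if (m == 0L) return(0)
  t <- sum(s1[match1] != s2[used2]) / 2
  (m / n1 + m / n2 + (m - t) / m) / 3
}

#' @rdname levenshtein
#' @export
jaro_winkler <- function(a, b, prefix_scale = 0.1, max_prefix = 4L,
                         boost_threshold = 0.7) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- rep(NA_real_, n)
  for (i in which(!is.na(a) & !is.na(b))) {
    sj <- .jaro_sim(a[i], b[i])
    if (sj > boost_threshold) {
      k <- min(max_prefix, nchar(a[i]), nchar(b[i]))
      l <- 0L
      while (l < k && substr(a[i], l + 1L, l + 1L) == substr(b[i], l + 1L, l + 1L)) {
        l <- l + 1L
      }
      sj <- sj + l * prefix_scale * (1 - sj)
    }
    out[i] <- sj
  }
  out
}

#' @rdname levenshtein
#' @export
jw_distance <- function(a, b) 1 - jaro_winkler(a, b)
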