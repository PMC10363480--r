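#' @include helix-finder.R physchem.R
NULL

#' Two-group t-test wrapper
#'
#' Welch unequal-variance t-test by default (pooled variance via
#' \code{pooled = TRUE}); one-sided tests specify the alternative
#' direction of the first sample relative to the second.
#'
#' @param a,b numeric samples, each of length at least 2
#' @param sided \code{"two"} or \code{"one"}
#' @param direction for one-sided tests: is \code{a} \code{"greater"} or
#'   \code{"less"} than \code{b} under the alternative?
#' @param pooled assume equal variances
#' @return list with \code{statistic}, \code{p_value}, \code{test},
#'   \code{alternative}, \code{df}
#' @examples
#' groupTTest(rnorm(10), rnorm(10, 2), sided = "one",
#'            direction = "less")$p_value
#' @export
groupTTest <- function(a, b, sided = c("two", "one"),
                       direction = c("greater", "less"), pooled = FALSE) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both samples have zero variance; t-test undefined")
  alt <- if (sided == "two") "two.sided" else direction
  tt <- stats::t.test(a, b, alternative = alt, var.equal = pooled)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       test = if (sided == "two") "T_TWO_SIDED" else "T_ONE_SIDED",
       alternative = alt, df = unname(tt$parameter))
}

#' Kruskal-Wallis omnibus with Dunn post hoc tests
#'
#' Runs the Kruskal-Wallis rank-sum test across all groups, followed by
#' pairwise Dunn z-tests on the mean ranks with a tie correction; pairwise
#' p-values are adjusted for multiplicity (Holm by default). With all
#' values tied across all groups the omnibus is undefined and reported as
#' such (NA p-value with a note) rather than erroring.
#'
#' The Dunn statistic for groups i, j is
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12}
#'  - \frac{\sum_s (t_s^3 - t_s)}{12(N-1)}\right)
#'  \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with two-sided normal p-values.
#'
#' @param groups named list of numeric samples (at least 3 for the
#'   omnibus)
#' @param correction multiplicity correction for the Dunn p-values
#' @return list with \code{omnibus} (statistic, df, p_value, note) and
#'   \code{pairwise} (data.frame: group1, group2, z, p_value, p_adjusted)
#' @examples
#' kruskalDunn(list(a = 1:10, b = 11:20, c = 21:30))$pairwise
#' @export
kruskalDunn <- function(groups, correction = c("holm", "bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(is.list(groups), length(groups) >= 2L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  if (length(unique(values)) == 1L) {
    omnibus <- list(statistic = NA_real_, df = length(groups) - 1L,
                    p_value = NA_real_,
                    note = "all values tied across all groups; omnibus undefined")
    pairwise <- data.frame(group1 = character(0), group2 = character(0),
                           z = numeric(0), p_value = numeric(0),
                           p_adjusted = numeric(0))
    return(list(omnibus = omnibus, pairwise = pairwise))
  }
  kw <- stats::kruskal.test(values, labels)
  omnibus <- list(statistic = unname(kw$statistic),
                  df = unname(kw$parameter), p_value = kw$p.value, note = "")
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  cmb <- utils::combn(names(groups), 2L)
  z <- apply(cmb, 2L, function(gg) {
    (mean_rank[[gg[1L]]] - mean_rank[[gg[2L]]]) /
      sqrt(s2 * (1 / n[[gg[1L]]] + 1 / n[[gg[2L]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  pairwise <- data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ], z = z,
                         p_value = p,
                         p_adjusted = stats::p.adjust(p, method = correction),
                         stringsAsFactors = FALSE)
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Per-class property table with group tests
#'
#' Joins helix metrics (\code{\link{helixMetrics}}) with physicochemical
#' features and tabulates, per peptide class, the distributions of the
#' salient targeting-peptide properties: evaluated length, amphipathic
#' helix fraction, upstream (pre-helix) stretch length, K and R
#' frequencies, and Boman index. For every pair of classes and every
#' property a Welch t-test is run; by default two-sided, or one-sided for
#' a designated pair (\code{one_sided_pair}) in the direction established
#' by a reference pair (\code{reference_pair}) on the same property, the
#' scheme used to compare small HA-RAMP preference sets along the trend
#' set by the targeting-peptide classes.
#'
#' @param metrics data.frame from \code{\link{helixMetrics}}
#' @param features data.frame with \code{peptide_id} and columns
#'   \code{freq_K}, \code{freq_R}, \code{boman} (any subset; missing ones
#'   are skipped)
#' @param sets data.frame with columns \code{peptide_id}, \code{set}
#' @param reference_pair,one_sided_pair optional character(2) of set
#'   names: test \code{one_sided_pair} one-sided in the direction the
#'   reference pair exhibits
#' @return list with \code{table} (per-set summary: n, mean, sd, median
#'   per property) and \code{tests} (data.frame: property, set1, set2,
#'   test, direction, statistic, p_value)
#' @export
tpPropertyTable <- function(metrics, features = NULL, sets,
                            reference_pair = NULL, one_sided_pair = NULL) {
  stopifnot(all(c("peptide_id", "set") %in% names(sets)))
  df <- merge(metrics, sets, by = "peptide_id")
  if (!is.null(features)) df <- merge(df, features, by = "peptide_id",
                                      all.x = TRUE)
  props <- intersect(c("length", "helix_fraction", "upstream_length",
                       "freq_K", "freq_R", "boman"), names(df))
  set_names <- unique(df$set)
  tab <- do.call(rbind, lapply(set_names, function(s) {
    sub <- df[df$set == s, , drop = FALSE]
    do.call(rbind, lapply(props, function(p) {
      v <- sub[[p]]
      data.frame(set = s, property = p, n = sum(!is.na(v)),
                 mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
                 median = stats::median(v, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tab) <- NULL
  tests <- NULL
  if (length(set_names) >= 2L) {
    pairs <- utils::combn(set_names, 2L)
    tests <- do.call(rbind, lapply(props, function(p) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
        s1 <- pairs[1L, k]; s2 <- pairs[2L, k]
        one_sided <- !is.null(one_sided_pair) &&
          setequal(c(s1, s2), one_sided_pair)
        if (one_sided && s1 != one_sided_pair[1L]) {
          # align the tested pair with the stated order so the direction
          # carried over from the reference pair applies to set1 vs set2
          tmp <- s1; s1 <- s2; s2 <- tmp
        }
        a <- df[[p]][df$set == s1]; b <- df[[p]][df$set == s2]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L) return(NULL)
        direction <- NA_character_
        if (one_sided) {
          ref <- reference_pair %||% c(s1, s2)
          ra <- df[[p]][df$set == ref[1L]]; rb <- df[[p]][df$set == ref[2L]]
          direction <- if (mean(ra, na.rm = TRUE) >= mean(rb, na.rm = TRUE))
            "greater" else "less"
        }
        res <- tryCatch(
          groupTTest(a, b, sided = if (one_sided) "one" else "two",
                     direction = if (one_sided) direction else "greater"),
          error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(property = p, set1 = s1, set2 = s2, test = res$test,
                   direction = direction, statistic = res$statistic,
                   p_value = res$p_value, stringsAsFactors = FALSE)
      }))
    }))
    rownames(tests) <- NULL
  }
  list(table = tab, tests = tests)
}
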