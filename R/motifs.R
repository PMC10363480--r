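#' @include peptide-core.R
NULL

.emptyHits <- function() {
  data.frame(peptide_id = character(0), rule = character(0),
             start = integer(0), width = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

.windowResidueMatrix <- function(res, window) {
  n <- length(res) - window + 1L
  if (n < 1L) return(NULL)
  # n x window matrix of residues per window
  matrix(res[outer(seq_len(n), 0:(window - 1L), `+`)], nrow = n)
}

#' Scan for FGLK TOC-interaction sites
#'
#' Applies the FGLK window rule to every 8-residue window: a window
#' qualifies when it contains F, one of \{P, G\}, one of \{K, R\}, one of
#' \{A, L, V\}, and neither D nor E. The relaxed FGLK-1 variant requires
#' only three of the four positive determinant classes (still excluding
#' D/E), accommodating the weaker F requirement observed in algal transit
#' peptides. Determinants are presence tests, not counts. Peptides shorter
#' than the window return an empty result with a message.
#'
#' @param x a \code{PeptideSet} or sequence string
#' @param relaxed use the FGLK-1 rule
#' @param window window width (default 8 residues)
#' @return data.frame of per-window hits (\code{peptide_id}, \code{rule},
#'   \code{start}, \code{width}, \code{score}); merge overlapping windows
#'   into sites with \code{\link{motifSites}}
#' @examples
#' scanFGLK("FPKALSTQ")
#' @export
scanFGLK <- function(x, relaxed = FALSE, window = 8L) {
  seqs <- if (is(x, "PeptideSet")) aaSequences(x) else
    stats::setNames(x, names(x) %||% "peptide")
  rule <- if (relaxed) "FGLK_1" else "FGLK"
  out <- lapply(names(seqs), function(id) {
    res <- .residues(seqs[[id]])
    wm <- .windowResidueMatrix(res, window)
    if (is.null(wm)) {
      message("peptide '", id, "' shorter than the ", window,
              "-residue window; no FGLK scan")
      return(.emptyHits())
    }
    has <- function(set) matrixStats_any(wm, set)
    n_classes <- has("F") + has(c("P", "G")) + has(c("K", "R")) +
      has(c("A", "L", "V"))
    acidic <- has(c("D", "E"))
    ok <- !acidic & n_classes >= (if (relaxed) 3L else 4L)
    if (!any(ok)) return(.emptyHits())
    data.frame(peptide_id = id, rule = rule, start = which(ok),
               width = window, score = NA_real_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# rowwise "any residue of `set` present" over a window matrix
matrixStats_any <- function(wm, set) {
  rowSums(matrix(wm %in% set, nrow = nrow(wm))) > 0L
}

#' Scan for Hsp70-binding sites
#'
#' Scores every \code{window}-residue stretch (default 7, the length of the
#' chaperone's peptide-binding core) by the sum of per-residue binding
#' affinities; windows scoring at least \code{threshold} are hits. With the
#' shipped synthetic affinity table, higher scores mean stronger predicted
#' binding, driven by hydrophobic (especially leucine-rich) windows and
#' suppressed by acidic residues.
#'
#' @param x a \code{PeptideSet} or sequence string
#' @param affinity named per-residue affinity values covering all 20
#'   residues
#' @param window window width
#' @param threshold minimum window score for a hit
#' @return data.frame of per-window hits with their scores
#' @export
scanHsp70 <- function(x, affinity = hsp70AffinityScale(), window = 7L,
                      threshold = 4) {
  .checkScale(affinity)
  seqs <- if (is(x, "PeptideSet")) aaSequences(x) else
    stats::setNames(x, names(x) %||% "peptide")
  out <- lapply(names(seqs), function(id) {
    res <- .residues(seqs[[id]])
    if (length(res) < window) return(.emptyHits())
    a <- affinity[res]
    cs <- c(0, cumsum(a))
    n <- length(res) - window + 1L
    score <- cs[window + seq_len(n)] - cs[seq_len(n)]
    ok <- score >= threshold
    if (!any(ok)) return(.emptyHits())
    data.frame(peptide_id = id, rule = "HSP70", start = which(ok),
               width = window, score = score[ok], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scan for N-terminal multi-arginine motifs
#'
#' Reports maximal runs of at least \code{min_run} consecutive arginines
#' starting within the first \code{n_term} residues, the N-terminal multi-R
#' feature discussed as a chloroplast-import determinant.
#'
#' @param x a \code{PeptideSet} or sequence string
#' @param n_term N-terminal region examined (residues)
#' @param min_run minimum run length
#' @return data.frame with one row per run (\code{start}, \code{width})
#' @examples
#' scanMultiR("MRRA")
#' @export
scanMultiR <- function(x, n_term = 15L, min_run = 2L) {
  seqs <- if (is(x, "PeptideSet")) aaSequences(x) else
    stats::setNames(x, names(x) %||% "peptide")
  out <- lapply(names(seqs), function(id) {
    res <- .residues(seqs[[id]])
    res <- res[seq_len(min(n_term, length(res)))]
    r <- rle(res == "R")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(.emptyHits())
    data.frame(peptide_id = id, rule = "MULTI_R", start = starts[keep],
               width = r$lengths[keep], score = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Merge overlapping motif windows into sites
#'
#' Overlapping qualifying windows of the same rule in the same peptide are
#' merged into maximal runs, so a cluster of windows counts as one reported
#' site; per-window detail stays available in the scanner output.
#'
#' @param hits a hits data.frame from one of the \code{scan*} functions
#' @return data.frame with columns \code{peptide_id}, \code{rule},
#'   \code{site_start}, \code{site_end}, \code{n_windows},
#'   \code{max_score}
#' @export
motifSites <- function(hits) {
  empty <- data.frame(peptide_id = character(0), rule = character(0),
                      site_start = integer(0), site_end = integer(0),
                      n_windows = integer(0), max_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  out <- lapply(split(hits, paste(hits$peptide_id, hits$rule)), function(h) {
    h <- h[order(h$start), , drop = FALSE]
    s <- h$start; e <- h$start + h$width - 1L
    grp <- cumsum(c(1L, as.integer(s[-1L] > cummax(e)[-length(e)])))
    do.call(rbind, lapply(split(seq_len(nrow(h)), grp), function(i)
      data.frame(peptide_id = h$peptide_id[1L], rule = h$rule[1L],
                 site_start = min(s[i]), site_end = max(e[i]),
                 n_windows = length(i),
                 max_score = if (all(is.na(h$score[i]))) NA_real_ else
                   max(h$score[i], na.rm = TRUE),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$peptide_id, out$rule, out$site_start), , drop = FALSE]
}
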