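#' @include peptide-core.R
NULL

#' Z-scale auto-cross-covariance (ACC) featurization
#'
#' Describes each peptide by 36 auto-cross-covariance terms of its three
#' Z-scale series. For scales \eqn{j, k \in \{1,2,3\}} and residue lag
#' \eqn{d \in \{1,\dots,\code{max\_lag}\}}:
#' \deqn{ACC_{j,k,d} = \frac{1}{N-d} \sum_{i=1}^{N-d}
#'   z_j(r_i)\, z_k(r_{i+d})}
#' Terms are uncentred products by default (\code{centered = TRUE}
#' subtracts each scale's within-sequence mean first) and ordered
#' lexicographically in (j, k, d); column names \code{acc_j_k_d} persist
#' the ordering.
#'
#' @param x a \code{PeptideSet} or a single sequence string
#' @param z Z-scale table (20 x 3 matrix, see \code{\link{zScaleTable}})
#' @param max_lag maximum residue lag (default 4, giving 36 terms)
#' @param centered subtract per-sequence scale means before forming
#'   products
#' @return \code{accVector}: a named numeric vector of \code{9 * max_lag}
#'   values (single peptide); \code{accMatrix}: a matrix with one row per
#'   peptide.
#' @examples
#' accVector("GIGKFLKSAK")[1:4]
#' @export
accVector <- function(x, z = zScaleTable(), max_lag = 4L, centered = FALSE) {
  if (is(x, "PeptideSet")) {
    if (length(x) != 1L)
      stop("accVector expects a single peptide; use accMatrix for sets")
    x <- aaSequences(x)[[1]]
  }
  res <- .residues(x)
  N <- length(res)
  if (N < max_lag + 1L)
    stop("peptide too short for ACC: need at least max_lag + 1 = ",
         max_lag + 1L, " residues, got ", N)
  zm <- z[res, , drop = FALSE]              # N x 3
  if (centered) zm <- sweep(zm, 2L, colMeans(zm))
  out <- numeric(9L * max_lag)
  nm <- character(9L * max_lag)
  pos <- 1L
  cross <- vector("list", max_lag)
  for (d in seq_len(max_lag))
    cross[[d]] <- crossprod(zm[1:(N - d), , drop = FALSE],
                            zm[(1 + d):N, , drop = FALSE]) / (N - d)
  for (j in 1:3) for (k in 1:3) for (d in seq_len(max_lag)) {
    out[pos] <- cross[[d]][j, k]
    nm[pos] <- paste("acc", j, k, d, sep = "_")
    pos <- pos + 1L
  }
  stats::setNames(out, nm)
}

#' @rdname accVector
#' @export
accMatrix <- function(x, z = zScaleTable(), max_lag = 4L, centered = FALSE) {
  stopifnot(is(x, "PeptideSet"))
  rows <- lapply(seq_len(length(x)), function(i)
    accVector(aaSequences(x)[[i]], z, max_lag, centered))
  m <- do.call(rbind, rows)
  rownames(m) <- peptideIds(x)
  m
}

#' Euclidean distance to the targeting-peptide ACC barycenter
#'
#' Computes the barycenter (coordinate-wise mean) of the reference set's
#' ACC vectors and each query's Euclidean distance to it, the similarity
#' measure used to rank candidate peptides against a targeting-peptide
#' reference cloud: smaller distances mean more TP-like physicochemistry.
#'
#' @param queries,reference \code{PeptideSet}s; all peptides must be long
#'   enough for ACC
#' @param ... passed to \code{\link{accMatrix}}
#' @return data.frame with columns \code{peptide_id}, \code{tp_distance}
#' @export
tpBarycenterDistance <- function(queries, reference, ...) {
  if (length(reference) == 0L) stop("reference set is empty")
  ref <- accMatrix(reference, ...)
  bary <- colMeans(ref)
  q <- accMatrix(queries, ...)
  data.frame(peptide_id = rownames(q),
             tp_distance = sqrt(rowSums(sweep(q, 2L, bary)^2)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Boman index
#'
#' Mean per-residue protein-interaction propensity: high values indicate a
#' peptide more likely to interact with proteins, low values with lipids.
#'
#' @param x a \code{PeptideSet} or sequence string
#' @param scale per-residue values (default \code{\link{bomanScale}})
#' @return named numeric vector, one value per peptide
#' @examples
#' bomanIndex("GIGKFLKS")
#' @export
bomanIndex <- function(x, scale = bomanScale()) {
  .checkScale(scale)
  seqs <- if (is(x, "PeptideSet")) aaSequences(x) else
    stats::setNames(x, names(x) %||% x)
  vapply(seqs, function(s) mean(scale[.residues(s)]), numeric(1))
}

#' Sliding-window charge profile and net charge
#'
#' Residue charges are K = R = +1, D = E = -1, others 0 (histidine
#' configurable). The profile value at position \eqn{i} is the summed
#' charge of the \code{window} residues starting there; windows truncated
#' at the C-terminus are dropped. The net charge is the whole-sequence sum.
#'
#' @param x a single-peptide \code{PeptideSet} or sequence string
#' @param window window width, residues
#' @param his_charge charge assigned to histidine (default 0)
#' @return list with \code{profile} (data.frame \code{position},
#'   \code{charge}) and \code{net_charge}
#' @examples
#' chargeProfile("KDKD", window = 2)$net_charge
#' @export
chargeProfile <- function(x, window = 10L, his_charge = 0) {
  if (is(x, "PeptideSet")) {
    stopifnot(length(x) == 1L)
    x <- aaSequences(x)[[1]]
  }
  window <- as.integer(window)
  stopifnot(window >= 1L)
  res <- .residues(x)
  ch <- numeric(length(res))
  ch[res %in% c("K", "R")] <- 1
  ch[res %in% c("D", "E")] <- -1
  ch[res == "H"] <- his_charge
  n_win <- length(res) - window + 1L
  prof <- if (n_win >= 1L) {
    cs <- c(0, cumsum(ch))
    data.frame(position = seq_len(n_win),
               charge = cs[window + seq_len(n_win)] - cs[seq_len(n_win)])
  } else data.frame(position = integer(0), charge = numeric(0))
  list(profile = prof, net_charge = sum(ch))
}

#' Per-peptide amino-acid frequency tables
#'
#' Computes the frequency of each of the 20 residues (count / length) for
#' every peptide in one or more named sets, the representation behind
#' K/R-frequency contrasts between peptide classes. Frequencies sum to 1
#' per peptide. An optional baseline (for example database-average
#' frequencies, supplied as configuration, never computed here) is attached
#' as the \code{"baseline"} attribute.
#'
#' @param sets a \code{PeptideSet} or named list of them
#' @param baseline optional named numeric of reference frequencies
#' @return data.frame with columns \code{set}, \code{peptide_id} and
#'   \code{freq_A} ... \code{freq_Y}
#' @examples
#' aaFrequencyTable(PeptideSet(c(p = "KKRR")))[, c("freq_K", "freq_R")]
#' @export
aaFrequencyTable <- function(sets, baseline = NULL) {
  if (is(sets, "PeptideSet")) sets <- list(set = sets)
  stopifnot(length(sets) > 0L, all(vapply(sets, is, logical(1), "PeptideSet")))
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  out <- do.call(rbind, lapply(names(sets), function(nm) {
    ps <- sets[[nm]]
    seqs <- aaSequences(ps)
    freq <- t(vapply(seqs, function(s) {
      r <- .residues(s)
      tabulate(match(r, AA20), nbins = 20L) / length(r)
    }, numeric(20)))
    colnames(freq) <- paste0("freq_", AA20)
    cbind(data.frame(set = nm, peptide_id = peptideIds(ps),
                     stringsAsFactors = FALSE),
          as.data.frame(freq, row.names = FALSE))
  }))
  rownames(out) <- NULL
  if (!is.null(baseline)) attr(out, "baseline") <- baseline
  out
}
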