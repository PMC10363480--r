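#' @include peptide-core.R
NULL

#' Per-residue hydrophobic moment of a helical-wheel window
#'
#' Places the residues of \code{window} at \code{delta}-degree intervals
#' (default 100 degrees per residue, i.e. 3.6 residues per alpha-helical
#' turn) and returns the magnitude of the vector sum of their
#' hydrophobicities, normalised per residue:
#' \deqn{\mu_H = \frac{1}{N}\left|\sum_{n=0}^{N-1} H(r_n)\,
#'   (\cos n\delta, \sin n\delta)\right|}
#' together with the direction of the moment (degrees, pointing towards the
#' hydrophobic face).
#'
#' @param window residue string of length >= 2
#' @param scale named hydrophobicity scale covering all residues present
#' @param delta wheel angle per residue, degrees
#' @return list with elements \code{mu} and \code{angle}
#' @examples
#' hydrophobicMoment("LKLLKKLLKKLLKLLKKL")$mu
#' @export
hydrophobicMoment <- function(window, scale = helixHydrophobicityScale(),
                              delta = 100) {
  res <- .residues(window)
  if (length(res) < 2L) stop("window must contain at least 2 residues")
  unknown <- setdiff(res, names(scale))
  if (length(unknown))
    stop("residue(s) not in scale: ", paste(unknown, collapse = ", "))
  h <- scale[res]
  theta <- (seq_along(res) - 1L) * delta * pi / 180
  vx <- sum(h * cos(theta)); vy <- sum(h * sin(theta))
  list(mu = sqrt(vx^2 + vy^2) / length(res),
       angle = atan2(vy, vx) * 180 / pi)
}

#' Configuration for the amphipathic-helix finder
#'
#' Tunable parameters of \code{\link{findAmphipathicHelices}}. The
#' qualification predicate for a candidate stretch is: length at least
#' \code{min_length}; per-residue hydrophobic moment at least \code{mu_min}
#' under \code{scale}; and both faces identifiable: among residues whose
#' wheel position lies within 90 degrees of the moment direction, at least
#' a fraction \code{hydrophobic_frac} belong to \code{hydrophobic_set},
#' while the opposite face holds at least \code{min_polar_opposite}
#' residues from \code{polar_set}.
#'
#' In addition, a qualifying stretch must be locally amphipathic: every
#' contiguous \code{min_length}-residue subwindow must reach a per-residue
#' moment of \code{mu_min_local}. Without this, two amphipathic helices
#' separated by a short indifferent spacer can merge into one long
#' "stretch" whose global moment still clears the threshold even though
#' the spacer has no face structure at all.
#'
#' @param min_length minimum helix length, residues (default 9, two and a
#'   half helical turns)
#' @param mu_min minimum per-residue hydrophobic moment (dimensionless on
#'   the Fauchere-Pliska scale; default 0.35)
#' @param mu_min_local minimum per-residue moment of every
#'   \code{min_length}-residue subwindow (default: \code{mu_min})
#' @param hydrophobic_frac minimum hydrophobic-face purity (default 0.6)
#' @param min_polar_opposite minimum polar residues on the opposite face
#' @param delta wheel angle per residue, degrees
#' @param scale hydrophobicity scale
#' @param hydrophobic_set,polar_set residue classes used by the face test
#' @return a named list
#' @export
helixConfig <- function(min_length = 9L, mu_min = 0.35,
                        mu_min_local = NULL,
                        hydrophobic_frac = 0.6, min_polar_opposite = 2L,
                        delta = 100,
                        scale = helixHydrophobicityScale(),
                        hydrophobic_set = c("L", "I", "V", "F", "M", "W", "Y", "A"),
                        polar_set = c("R", "K", "D", "E", "S", "T", "N",
                                      "Q", "H", "G", "P")) {
  list(min_length = as.integer(min_length), mu_min = mu_min,
       mu_min_local = mu_min_local %||% mu_min,
       hydrophobic_frac = hydrophobic_frac,
       min_polar_opposite = as.integer(min_polar_opposite),
       delta = delta, scale = scale,
       hydrophobic_set = hydrophobic_set, polar_set = polar_set)
}

# Angular distance in degrees, in [0, 180].
.angDist <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Face test for window [s, e] given the moment direction in the global
# wheel frame. Returns the face index lists or NULL if unqualified.
.faceTest <- function(res, s, e, angle_global, cfg) {
  idx <- s:e
  ang <- (idx - 1L) * cfg$delta %% 360
  on_hydro <- .angDist(ang, angle_global) <= 90
  hydro_idx <- idx[on_hydro]
  philic_idx <- idx[!on_hydro]
  if (!length(hydro_idx) || !length(philic_idx)) return(NULL)
  frac <- mean(res[hydro_idx] %in% cfg$hydrophobic_set)
  npol <- sum(res[philic_idx] %in% cfg$polar_set)
  if (frac >= cfg$hydrophobic_frac && npol >= cfg$min_polar_opposite)
    list(hydro = hydro_idx, philic = philic_idx)
  else NULL
}

# Recursive longest-first search on [lo, hi]; cx/cy are prefix sums of
# H * (cos, sin) over the whole sequence in the global wheel frame, so any
# window moment is a prefix difference. cum_bad counts, per local-window
# start, the subwindows failing the local moment threshold, so the local
# amphipathicity of any stretch is one subtraction.
.searchSegment <- function(res, cx, cy, cum_bad, lo, hi, cfg, acc) {
  seg_len <- hi - lo + 1L
  if (seg_len < cfg$min_length) return(acc)
  starts <- integer(0); ends <- integer(0)
  for (len in seq(from = min(seg_len, length(res)), to = cfg$min_length)) {
    s <- lo:(hi - len + 1L)
    starts <- c(starts, s); ends <- c(ends, s + len - 1L)
  }
  vx <- cx[ends + 1L] - cx[starts]
  vy <- cy[ends + 1L] - cy[starts]
  lens <- ends - starts + 1L
  mu <- sqrt(vx^2 + vy^2) / lens
  local_ok <- cum_bad[ends - cfg$min_length + 2L] - cum_bad[starts] == 0L
  keep <- which(mu >= cfg$mu_min & local_ok)
  if (!length(keep)) return(acc)
  ord <- keep[order(-lens[keep], -mu[keep], starts[keep])]
  for (w in ord) {
    angle <- atan2(vy[w], vx[w]) * 180 / pi
    faces <- .faceTest(res, starts[w], ends[w], angle, cfg)
    if (!is.null(faces)) {
      local_angle <- (angle - (starts[w] - 1L) * cfg$delta) %% 360
      acc[[length(acc) + 1L]] <- list(
        start = starts[w], end = ends[w], mu_h = mu[w], angle = local_angle,
        face_hydrophobic = faces$hydro, face_hydrophilic = faces$philic)
      acc <- .searchSegment(res, cx, cy, cum_bad, lo, starts[w] - 1L, cfg,
                            acc)
      acc <- .searchSegment(res, cx, cy, cum_bad, ends[w] + 1L, hi, cfg,
                            acc)
      return(acc)
    }
  }
  acc
}

.profileFromAnnotations <- function(id, ann, limit) {
  if (nrow(ann)) ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  covered <- if (nrow(ann)) sum(ann$end - ann$start + 1L) else 0L
  helix_free <- nrow(ann) == 0L
  upstream <- if (helix_free) as.numeric(limit) else {
    lens <- ann$end - ann$start + 1L
    best <- which(lens == max(lens))
    ann$start[best[1L]] - 1
  }
  new("HelixProfile", peptide_id = id, annotations = ann,
      helix_fraction = covered / limit, upstream_length = upstream,
      evaluation_limit = as.integer(limit), helix_free = helix_free)
}

#' Find non-overlapping amphipathic helices in a peptide
#'
#' Scans a peptide for the longest sequence stretch with identifiable
#' hydrophobic and hydrophilic helical-wheel faces (see
#' \code{\link{helixConfig}} for the qualification predicate), records it,
#' masks it, and recurses on both flanks, so that multiple non-overlapping
#' helices can be annotated. Ties between equally long qualifying stretches
#' are broken by higher hydrophobic moment, then by the leftmost start, so
#' the result is deterministic for a fixed configuration.
#'
#' For targeting peptides the search can be restricted to the presequence
#' (\code{limitCleavage}). Externally established helices (for example from
#' an NMR structure) can be injected via \code{external}; they replace the
#' prediction for that peptide and are labelled \code{EXTERNAL}.
#'
#' @param x a \code{PeptideSet} (profiles are computed per peptide) or a
#'   single sequence string
#' @param config a \code{\link{helixConfig}} list
#' @param limitCleavage when TRUE, peptides with a cleavage index are
#'   evaluated only up to it
#' @param external optional data.frame with columns \code{peptide_id},
#'   \code{start}, \code{end}; rows matching a peptide id override its
#'   prediction
#' @return a named list of \linkS4class{HelixProfile} objects (or a single
#'   profile for a one-peptide input string)
#' @examples
#' p <- makeAmphipathicPeptide(18, seed = 1)
#' findAmphipathicHelices(p)[[1]]
#' @export
findAmphipathicHelices <- function(x, config = helixConfig(),
                                   limitCleavage = TRUE, external = NULL) {
  single <- is.character(x)
  if (single) x <- PeptideSet(stats::setNames(x, "peptide"))
  stopifnot(is(x, "PeptideSet"))
  ids <- peptideIds(x)
  seqs <- aaSequences(x)
  cl <- cleavageIndex(x)
  out <- vector("list", length(x))
  names(out) <- ids
  for (i in seq_along(out)) {
    res <- .residues(seqs[i])
    limit <- if (limitCleavage && !is.na(cl[i])) min(cl[i], length(res))
             else length(res)
    ext <- if (!is.null(external))
      external[external$peptide_id == ids[i], , drop = FALSE]
    else NULL
    if (!is.null(ext) && nrow(ext)) {
      ann <- do.call(rbind, lapply(seq_len(nrow(ext)), function(k) {
        s <- ext$start[k]; e <- ext$end[k]
        hm <- hydrophobicMoment(substr(seqs[i], s, e), config$scale,
                                config$delta)
        data.frame(start = s, end = e, mu_h = hm$mu, angle = hm$angle,
                   source = "EXTERNAL",
                   face_hydrophobic = "", face_hydrophilic = "",
                   stringsAsFactors = FALSE)
      }))
      out[[i]] <- .profileFromAnnotations(ids[i], ann, limit)
      next
    }
    h <- config$scale[res]
    if (anyNA(h))
      stop("record '", ids[i], "': residue not covered by the scale")
    theta <- (seq_along(res) - 1L) * config$delta * pi / 180
    cx <- c(0, cumsum(h * cos(theta)))
    cy <- c(0, cumsum(h * sin(theta)))
    ml <- config$min_length
    n_loc <- length(res) - ml + 1L
    hits <- if (n_loc >= 1L) {
      ls <- seq_len(n_loc)
      lmu <- sqrt((cx[ls + ml] - cx[ls])^2 + (cy[ls + ml] - cy[ls])^2) / ml
      cum_bad <- c(0L, cumsum(lmu < config$mu_min_local))
      .searchSegment(res, cx, cy, cum_bad, 1L, limit, config, list())
    } else list()
    ann <- if (length(hits)) {
      data.frame(
        start = vapply(hits, `[[`, integer(1), "start"),
        end = vapply(hits, `[[`, integer(1), "end"),
        mu_h = vapply(hits, `[[`, numeric(1), "mu_h"),
        angle = vapply(hits, `[[`, numeric(1), "angle"),
        source = "PREDICTED",
        face_hydrophobic = vapply(hits, function(a)
          paste(a$face_hydrophobic, collapse = ","), character(1)),
        face_hydrophilic = vapply(hits, function(a)
          paste(a$face_hydrophilic, collapse = ","), character(1)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(start = integer(0), end = integer(0), mu_h = numeric(0),
                 angle = numeric(0), source = character(0),
                 face_hydrophobic = character(0),
                 face_hydrophilic = character(0))
    }
    out[[i]] <- .profileFromAnnotations(ids[i], ann, limit)
  }
  if (single) out[[1L]] else out
}

#' @rdname HelixProfile-class
#' @export
setMethod("helixAnnotations", "HelixProfile",
          function(object) object@annotations)

#' @rdname HelixProfile-class
#' @export
setMethod("helixFraction", "HelixProfile",
          function(object) object@helix_fraction)

#' @rdname HelixProfile-class
#' @export
setMethod("upstreamLength", "HelixProfile",
          function(object) object@upstream_length)

#' @rdname HelixProfile-class
#' @export
setMethod("show", "HelixProfile", function(object) {
  cat("HelixProfile for", object@peptide_id, "(evaluated length",
      object@evaluation_limit, "residues)\n")
  if (nrow(object@annotations)) {
    a <- object@annotations
    for (i in seq_len(nrow(a)))
      cat(sprintf("  helix %d: %d-%d  muH = %.3f  (%s)\n", i, a$start[i],
                  a$end[i], a$mu_h[i], a$source[i]))
  } else cat("  no amphipathic helix\n")
  cat(sprintf("  helix fraction %.2f, upstream length %g%s\n",
              object@helix_fraction, object@upstream_length,
              if (object@helix_free) " (helix-free convention)" else ""))
  invisible(object)
})

#' Per-peptide helix metrics
#'
#' Tabulates, for each profile, the evaluated length (up to the cleavage
#' site for targeting peptides), the amphipathic-helix fraction, the length
#' of the sequence stretch upstream of the longest predicted helix, the
#' number of helices, and the longest helix length. Helix-free peptides
#' report the whole evaluated length as upstream (flagged by
#' \code{helix_free}), placing them at the maximally unstructured end of
#' the axis.
#'
#' @param profiles list of \linkS4class{HelixProfile} (from
#'   \code{\link{findAmphipathicHelices}})
#' @return data.frame with one row per peptide
#' @export
helixMetrics <- function(profiles) {
  if (is(profiles, "HelixProfile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    a <- p@annotations
    data.frame(
      peptide_id = p@peptide_id,
      length = p@evaluation_limit,
      helix_fraction = p@helix_fraction,
      upstream_length = p@upstream_length,
      n_helices = nrow(a),
      longest_helix_length = if (nrow(a)) max(a$end - a$start + 1L) else 0L,
      helix_free = p@helix_free,
      stringsAsFactors = FALSE)
  }))
}
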