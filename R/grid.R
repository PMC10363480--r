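#' @include AllGenerics.R
NULL

# Ordered targeting levels: NONE < PARTIAL < FULL.
.levelRank <- function(x) match(x, TARGETING_LEVELS) - 1L

#' Load a construct-targeting grid
#'
#' Reads a TSV of per-construct organelle-targeting calls (columns
#' \code{row}, \code{column}, \code{mito}, \code{chloro}, optionally
#' \code{core} and \code{note}) into a validated
#' \linkS4class{TargetingGrid}. Unknown coordinates, malformed call values
#' and duplicate cells are errors naming the offending cell. The packaged
#' fixture \code{fig2_grid.tsv} holds the curated calls for the chimeric
#' HA-RAMP construct series (rows A-L, columns a-s).
#'
#' @param path TSV file
#' @return a \code{TargetingGrid}
#' @examples
#' grid <- loadGrid(system.file("extdata", "fig2_grid.tsv",
#'                              package = "chimeraTP"))
#' grid
#' @export
loadGrid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(g) == 0L) {
    g <- data.frame(row = character(0), column = character(0),
                    core = character(0), mito = character(0),
                    chloro = character(0), note = character(0),
                    stringsAsFactors = FALSE)
    return(new("TargetingGrid", calls = g))
  }
  need <- c("row", "column", "mito", "chloro")
  if (!all(need %in% names(g)))
    stop("grid TSV needs columns: ", paste(need, collapse = ", "))
  if (!("core" %in% names(g)))
    g$core <- unname(gridColumnMap()[g$column])
  if (!("note" %in% names(g))) g$note <- ""
  bad <- !(g$mito %in% TARGETING_LEVELS) | !(g$chloro %in% TARGETING_LEVELS)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("malformed targeting call at cell (", g$row[i], ", ", g$column[i],
         "): mito='", g$mito[i], "', chloro='", g$chloro[i], "'")
  }
  new("TargetingGrid",
      calls = g[, c("row", "column", "core", "mito", "chloro", "note")])
}

#' @rdname TargetingGrid-class
#' @export
setMethod("gridCalls", "TargetingGrid", function(object) object@calls)

#' @rdname TargetingGrid-class
#' @export
setMethod("show", "TargetingGrid", function(object) {
  g <- object@calls
  cat("TargetingGrid with", nrow(g), "cell(s)\n")
  if (nrow(g)) {
    cat("  rows:", paste(sort(unique(g$row)), collapse = ""), "\n")
    cat("  columns:", paste(sort(unique(g$column)), collapse = ""), "\n")
    both <- .levelRank(g$mito) > 0L & .levelRank(g$chloro) > 0L
    cat("  cells with mito targeting:", sum(.levelRank(g$mito) > 0L),
        "| chloro:", sum(.levelRank(g$chloro) > 0L),
        "| dual:", sum(both), "\n")
  }
  invisible(object)
})

.gridLookup <- function(g, row, column) {
  hit <- g$row == row & g$column == column
  if (!any(hit)) NULL else g[which(hit)[1L], , drop = FALSE]
}

# The K/R row pairs of the modification scheme.
KR_ROW_PAIRS <- list(c("A", "B"), c("C", "D"), c("E", "F"),
                     c("G", "H"), c("I", "J"), c("K", "L"))

#' Compare K-variant and R-variant construct rows
#'
#' For every K/R row pair of the modification scheme ((A,B), (C,D), (E,F),
#' (G,H), (I,J), (K,L)) and each requested column, classifies the effect
#' of the K-to-R switch on targeting of the chosen organelle:
#' \code{GAIN} (NONE to PARTIAL or FULL), \code{IMPROVE} (PARTIAL to
#' FULL), \code{LOSS} (to NONE), \code{DECREASE} (FULL to PARTIAL) or
#' \code{UNCHANGED}. A gain or improvement is additionally flagged
#' \code{dual_gain} when the R-variant cell targets both organelles at
#' least partially while the K-variant cell did not. Pairs with a missing
#' cell are skipped with a warning.
#'
#' @param grid a \code{TargetingGrid}
#' @param organelle \code{"MITO"} or \code{"CHLORO"}
#' @param columns grid columns compared (default a-m, the HA-RAMP cores)
#' @return data.frame with one row per evaluated (pair, column); the
#'   \code{"counts"} attribute tallies each change class, gains +
#'   improvements, and dual gains
#' @examples
#' grid <- loadGrid(system.file("extdata", "fig2_grid.tsv",
#'                              package = "chimeraTP"))
#' attr(compareKRPairs(grid, "MITO"), "counts")$gains_plus_improvements
#' @export
compareKRPairs <- function(grid, organelle = c("MITO", "CHLORO"),
                           columns = letters[1:13]) {
  organelle <- match.arg(organelle)
  g <- gridCalls(grid)
  field <- if (organelle == "MITO") "mito" else "chloro"
  rows <- list()
  for (pair in KR_ROW_PAIRS) for (col in columns) {
    kc <- .gridLookup(g, pair[1L], col)
    rc <- .gridLookup(g, pair[2L], col)
    if (is.null(kc) || is.null(rc)) {
      warning("missing cell for pair ", pair[1L], pair[2L], " column ", col,
              "; skipped", call. = FALSE)
      next
    }
    a <- .levelRank(kc[[field]]); b <- .levelRank(rc[[field]])
    change <- if (a == b) "UNCHANGED"
      else if (a == 0L && b > 0L) "GAIN"
      else if (a == 1L && b == 2L) "IMPROVE"
      else if (b == 0L) "LOSS"
      else "DECREASE"
    k_dual <- .levelRank(kc$mito) > 0L && .levelRank(kc$chloro) > 0L
    r_dual <- .levelRank(rc$mito) > 0L && .levelRank(rc$chloro) > 0L
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste0(pair[1L], pair[2L]), column = col,
      k_call = kc[[field]], r_call = rc[[field]], change = change,
      dual_gain = change %in% c("GAIN", "IMPROVE") && r_dual && !k_dual,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  counts <- as.list(table(factor(out$change,
    levels = c("GAIN", "IMPROVE", "LOSS", "DECREASE", "UNCHANGED"))))
  counts <- lapply(counts, as.integer)
  counts$gains_plus_improvements <- counts$GAIN + counts$IMPROVE
  counts$dual_gains <- sum(out$dual_gain)
  counts$n_evaluated <- nrow(out)
  attr(out, "counts") <- counts
  out
}

#' Tally grid cells satisfying a predicate
#'
#' Counts, over the given rows and columns, the cells whose targeting call
#' satisfies \code{predicate}, reporting the denominator (cells present).
#'
#' @param grid a \code{TargetingGrid}
#' @param rows row letters
#' @param predicate function of two strings (\code{mito}, \code{chloro}
#'   call values) returning TRUE/FALSE; see \code{\link{atLeastPartial}}
#' @param columns column letters (default a-m)
#' @return list with \code{count} and \code{denominator}
#' @examples
#' grid <- loadGrid(system.file("extdata", "fig2_grid.tsv",
#'                              package = "chimeraTP"))
#' tallyGrid(grid, c("K", "L"),
#'           function(m, c) atLeastPartial(c))  # 22 of 26
#' @export
tallyGrid <- function(grid, rows, predicate, columns = letters[1:13]) {
  g <- gridCalls(grid)
  sel <- g[g$row %in% rows & g$column %in% columns, , drop = FALSE]
  if (nrow(sel) == 0L) return(list(count = 0L, denominator = 0L))
  hit <- mapply(predicate, sel$mito, sel$chloro)
  list(count = sum(hit), denominator = nrow(sel))
}

#' @rdname tallyGrid
#' @param call a targeting call value
#' @export
atLeastPartial <- function(call) .levelRank(call) >= 1L

#' Per-core attribution of targeting outcomes
#'
#' Asks which core peptides account for the observed targeting: for each
#' organelle, counts the targeting constructs (call at least PARTIAL) per
#' column over rows A-L, each column's share of the total, and the
#' cumulative shares of the mitochondrion-preferring ("mt set": B2I, R2G,
#' MII) and chloroplast-preferring ("cp set": E1S, LCA, SIM, B15, EHF)
#' core sets. For the chloroplast the cp-set share is also reported with
#' rows K/L excluded, since the cTP-N/cTP-C combination generates
#' chloroplast targeting across most cores.
#'
#' @param grid a \code{TargetingGrid}
#' @param columns columns included (default a-m)
#' @param mt_set,cp_set core ids of the two preference sets
#' @return list with \code{per_column} (data.frame: column, core,
#'   mito_count, chloro_count, mito_share, chloro_share),
#'   \code{mt_set_mito_share}, \code{cp_set_chloro_share} and
#'   \code{cp_set_chloro_share_excl_KL}
#' @export
specificitySummary <- function(grid, columns = letters[1:13],
                               mt_set = c("B2I", "R2G", "MII"),
                               cp_set = c("E1S", "LCA", "SIM", "B15", "EHF")) {
  g <- gridCalls(grid)
  g <- g[g$column %in% columns, , drop = FALSE]
  map <- gridColumnMap()
  per <- do.call(rbind, lapply(columns, function(col) {
    cells <- g[g$column == col, , drop = FALSE]
    data.frame(column = col, core = unname(map[col]),
               mito_count = sum(.levelRank(cells$mito) > 0L),
               chloro_count = sum(.levelRank(cells$chloro) > 0L),
               stringsAsFactors = FALSE)
  }))
  per$mito_share <- per$mito_count / max(1L, sum(per$mito_count))
  per$chloro_share <- per$chloro_count / max(1L, sum(per$chloro_count))
  noKL <- g[!(g$row %in% c("K", "L")), , drop = FALSE]
  chloro_noKL <- vapply(columns, function(col)
    sum(.levelRank(noKL$chloro[noKL$column == col]) > 0L), integer(1))
  list(per_column = per,
       mt_set_mito_share = sum(per$mito_share[per$core %in% mt_set]),
       cp_set_chloro_share = sum(per$chloro_share[per$core %in% cp_set]),
       cp_set_chloro_share_excl_KL =
         sum(chloro_noKL[unname(map[columns]) %in% cp_set]) /
           max(1L, sum(chloro_noKL)))
}
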