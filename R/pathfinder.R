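#' Jaccard dissimilarity of two interface contact matrices
#'
#' `1 - |a & b| / |a | b|`; two empty matrices are identical (0). Used as
#' the metric behind "the interface contact matrix changes slowly along the
#' pathway".
#'
#' @param a,b logical contact matrices of identical shape.
#' @return value in \[0, 1\].
#' @export
contact_dissimilarity <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("contact matrices must have the same shape")
  u <- sum(a | b)
  if (u == 0) return(0)
  1 - sum(a & b) / u
}

#' Umbrella window specification
#'
#' Evenly spaced window centers along lambda' with a common bias force
#' constant (`k * d^2` convention). The defaults mirror the pathway
#' protocol: 16 windows, 3 seed structures per window.
#'
#' @param n_windows number of windows (default 16).
#' @param lam_lo,lam_hi first and last window center (lambda', Angstrom).
#' @param k_bias harmonic bias force constant, kcal/mol/A^2. The default
#'   0.3 gives adjacent-window histogram overlap above 10% at the default
#'   1.5 A spacing at 300 K.
#' @param n_seeds seed structures per window (default 3).
#' @return data.frame of class `window_spec` with columns `index`,
#'   `center`, `k`; attributes `n_seeds`.
#' @export
window_spec <- function(n_windows = 16, lam_lo = 0, lam_hi = 22.5,
                        k_bias = 0.3, n_seeds = 3) {
  stopifnot(n_windows >= 2, lam_hi > lam_lo, k_bias > 0)
  out <- data.frame(index = seq_len(n_windows),
                    center = seq(lam_lo, lam_hi, length.out = n_windows),
                    k = k_bias)
  structure(out, n_seeds = n_seeds, class = c("window_spec", "data.frame"))
}

#' Assign ensemble frames to umbrella windows
#'
#' Each frame joins the window whose center is nearest to its lambda'
#' value, provided it lies within the window's catchment (half the spacing
#' to the adjacent centers). A frame exactly between two centers joins the
#' lower-index window; frames outside every catchment stay unassigned.
#'
#' @param lamp per-frame lambda' values, Angstrom.
#' @param windows a [window_spec()] (or numeric vector of centers).
#' @return list of integer frame-index vectors, one per window, with
#'   attribute `unassigned`.
#' @export
assign_windows <- function(lamp, windows) {
  centers <- if (is.data.frame(windows)) windows$center else as.numeric(windows)
  k <- length(centers)
  stopifnot(k >= 2, all(diff(centers) > 0))
  edges <- c(centers[1] - diff(centers[1:2]) / 2,
             (centers[-k] + centers[-1]) / 2,
             centers[k] + diff(centers[(k - 1):k]) / 2)
  # intervals (edge_i, edge_{i+1}]: an exact midpoint joins the lower window
  bin <- findInterval(lamp, edges, left.open = TRUE, rightmost.closed = FALSE)
  bin[lamp <= edges[1] | lamp > edges[k + 1]] <- NA
  pools <- lapply(seq_len(k), function(i) which(!is.na(bin) & bin == i))
  empty <- which(lengths(pools) == 0)
  if (length(empty))
    stop(sprintf("no candidate frames for window(s) %s (lambda' near %s A): insufficient sampling along the pathway",
                 paste(empty, collapse = ", "),
                 paste(sprintf("%.1f", centers[empty]), collapse = ", ")))
  attr(pools, "unassigned") <- which(is.na(bin))
  pools
}

#' Select binding-pathway seed structures by dynamic programming
#'
#' Picks one candidate frame per window so that the interface contact
#' matrix changes as slowly as possible along the pathway: the chain
#' minimizing the sum of adjacent-window Jaccard dissimilarities, found
#' exactly by dynamic programming over the (capped) candidate pools. The
#' remaining `n_seeds - 1` seeds per window are the chain member's nearest
#' in-pool neighbors by contact dissimilarity.
#'
#' @param pools list of candidate frame-index vectors per window (see
#'   [assign_windows()]).
#' @param contacts list of logical contact matrices indexed by frame id
#'   (see [contact_map()]).
#' @param n_seeds seed structures per window (default 3).
#' @param weights optional per-frame statistical weights; pools larger than
#'   `pool_cap` are truncated to the top-weight candidates.
#' @param pool_cap maximum candidates per window considered (default 50).
#' @return object of class `path_selection`: data.frame `windows` (window,
#'   main seed frame, additional seeds), `score` (total dissimilarity of
#'   the main chain), `chain` (frame ids of the optimal chain).
#' @export
pick_path <- function(pools, contacts, n_seeds = 3, weights = NULL,
                      pool_cap = 50) {
  k <- length(pools)
  if (any(lengths(pools) == 0)) stop("every window pool must be non-empty")
  pools <- lapply(pools, function(p) {
    if (!is.null(weights) && length(p) > pool_cap)
      p[order(weights[p], decreasing = TRUE)[seq_len(pool_cap)]]
    else if (length(p) > pool_cap) p[seq_len(pool_cap)] else p
  })
  # dynamic programme over windows
  cost <- lapply(pools, function(p) rep(Inf, length(p)))
  back <- lapply(pools, function(p) rep(NA_integer_, length(p)))
  cost[[1]] <- rep(0, length(pools[[1]]))
  for (wnd in 2:k) {
    prev <- pools[[wnd - 1]]; cur <- pools[[wnd]]
    d <- matrix(0, length(prev), length(cur))
    for (i in seq_along(prev)) for (j in seq_along(cur))
      d[i, j] <- contact_dissimilarity(contacts[[prev[i]]], contacts[[cur[j]]])
    tot <- cost[[wnd - 1]] + d          # recycles cost down columns
    back[[wnd]] <- apply(tot, 2, which.min)
    cost[[wnd]] <- apply(tot, 2, min)
  }
  end <- which.min(cost[[k]])
  sel <- integer(k)
  sel[k] <- end
  for (wnd in k:2) sel[wnd - 1] <- back[[wnd]][sel[wnd]]
  chain <- vapply(seq_len(k), function(wnd) pools[[wnd]][sel[wnd]], integer(1))
  score <- sum(vapply(seq_len(k - 1), function(wnd)
    contact_dissimilarity(contacts[[chain[wnd]]], contacts[[chain[wnd + 1]]]),
    numeric(1)))
  seeds <- vector("list", k)
  for (wnd in seq_len(k)) {
    p <- pools[[wnd]]
    main <- chain[wnd]
    others <- setdiff(p, main)
    if (length(others) && n_seeds > 1) {
      dd <- vapply(others, function(f)
        contact_dissimilarity(contacts[[f]], contacts[[main]]), numeric(1))
      extra <- others[order(dd)][seq_len(min(n_seeds - 1, length(others)))]
    } else extra <- integer(0)
    seeds[[wnd]] <- c(main, extra)
  }
  structure(list(windows = data.frame(window = seq_len(k), main = chain),
                 seeds = seeds, score = score, chain = chain),
            class = "path_selection")
}

#' @export
print.path_selection <- function(x, ...) {
  k <- nrow(x$windows)
  cat(sprintf("Binding-pathway selection: %d windows, %d seeds each\n",
              k, length(x$seeds[[1]])))
  cat(sprintf("  total contact-dissimilarity score of the chain: %.3f (mean %.3f per step)\n",
              x$score, x$score / (k - 1)))
  invisible(x)
}
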