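# Distance time series between named selections, normalized probability
# distributions, and peak finding.

#' Select a single named atom
#'
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param name atom name (e.g. "O", "H", "CA").
#' @return selection object for [distance_series()].
#' @export
select_atom <- function(chain, resno, name) {
  structure(list(type = "atom", chain = chain, resno = as.integer(resno),
                 name = name), class = "traj_selection")
}

#' Select an aromatic ring (resolved per frame to its center of mass)
#'
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param which ring index within the residue (TRP has two; default 1).
#' @param ring_templates optional extra templates for nonstandard aromatic
#'   residues, as in [find_aromatic_rings()].
#' @return selection object for [distance_series()].
#' @export
select_ring <- function(chain, resno, which = 1L, ring_templates = NULL) {
  structure(list(type = "ring", chain = chain, resno = as.integer(resno),
                 which = as.integer(which), ring_templates = ring_templates),
            class = "traj_selection")
}

# Resolve a selection to per-frame points: returns F x 3 matrix.
.resolve_selection <- function(traj, sel) {
  stopifnot(inherits(sel, "traj_selection"))
  top <- traj$topology
  ri <- residue_serial(top, sel$chain, sel$resno)
  rng <- top$residues$first_atom[ri]:top$residues$last_atom[ri]
  nf <- n_frames(traj)
  if (sel$type == "atom") {
    hit <- rng[trimws(top$atoms$name[rng]) == sel$name]
    if (length(hit) != 1L)
      stop("selection ", sel$chain, sel$resno, ":", sel$name, " matched ",
           length(hit), " atom(s): ",
           paste(trimws(top$atoms$name[rng]), collapse = " "))
    t(traj$coords[hit, , , drop = TRUE])
  } else {
    rings <- find_aromatic_rings(top, sel$ring_templates)
    mine <- Filter(function(r) r$residue == ri, rings)
    if (length(mine) < sel$which)
      stop("residue ", sel$chain, sel$resno, " has ", length(mine),
           " ring(s); requested ring ", sel$which)
    ring <- mine[[sel$which]]
    m <- element_mass(top$atoms$element[ring$atoms])
    out <- matrix(NA_real_, nf, 3)
    for (f in seq_len(nf))
      out[f, ] <- center_of_mass(traj$coords[ring$atoms, , f, drop = TRUE], m)
    out
  }
}

#' Per-frame distance between two selections
#'
#' Each selection resolves to a single atom or an aromatic ring (replaced per
#' frame by its mass-weighted center of mass); distances use the minimum
#' image when the trajectory carries a box.
#'
#' @param traj an [md_trajectory()].
#' @param sel_a,sel_b selections from [select_atom()] or [select_ring()].
#' @param label optional series label.
#' @return object of class `"distance_series"`: numeric vector of per-frame
#'   distances (Angstrom) with a `label` attribute.
#' @export
distance_series <- function(traj, sel_a, sel_b, label = NULL) {
  pa <- .resolve_selection(traj, sel_a)
  pb <- .resolve_selection(traj, sel_b)
  d <- pa - pb
  if (!is.null(traj$box))
    for (k in 1:3) d[, k] <- d[, k] - traj$box[k] * round(d[, k] / traj$box[k])
  out <- sqrt(rowSums(d^2))
  structure(out, class = "distance_series",
            label = if (is.null(label)) "distance" else label)
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance_series '%s': %d frame(s), mean %.3f A (range %.3f-%.3f)\n",
              attr(x, "label"), length(x), mean(x), min(x), max(x)))
  invisible(x)
}

#' Normalized distance histogram
#'
#' Bin edges are aligned to absolute multiples of `bin_width` (so the binning
#' does not depend on the data minimum) and probabilities sum to 1.
#'
#' @param series a [distance_series()] or numeric vector of distances.
#' @param bin_width bin width in Angstrom (default 0.1).
#' @return object of class `"distance_distribution"`: list with `edges`
#'   (length B+1), `centers` (length B), `prob` (length B).
#' @export
distance_histogram <- function(series, bin_width = 0.1) {
  x <- as.numeric(series)
  if (!length(x)) stop("empty distance series")
  if (bin_width <= 0) stop("bin width must be positive")
  lo <- floor(min(x) / bin_width)
  hi <- ceiling(max(x) / bin_width)
  if (hi == lo) hi <- lo + 1L   # all values on a bin edge
  edges <- (lo:hi) * bin_width
  bin <- pmin(pmax(floor(x / bin_width) - lo + 1, 1L), hi - lo)
  counts <- tabulate(bin, nbins = hi - lo)
  structure(list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
                 prob = counts / sum(counts),
                 label = attr(series, "label")),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  i <- which.max(x$prob)
  cat(sprintf("distance_distribution: %d bin(s) of %.3g A; mode %.2f A (p = %.3f)\n",
              length(x$prob), diff(x$edges[1:2]), x$centers[i], x$prob[i]))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, main = NULL, ...) {
  graphics::plot(x$centers, x$prob, type = "h", lwd = 3,
                 xlab = "distance (A)", ylab = "probability",
                 main = if (is.null(main)) attr(x, "label") else main, ...)
  invisible(x)
}

#' Find prominent peaks of a distance distribution
#'
#' Local maxima are ranked by topographic prominence (height above the higher
#' of the two saddles separating the peak from higher terrain, extending to
#' the distribution edges); peaks with prominence below `min_prominence`
#' (a fraction of probability mass) are discarded. A distribution is
#' operationally unimodal when exactly one peak is returned.
#'
#' @param dist a [distance_histogram()] result.
#' @param min_prominence minimum prominence in [0, 1] (default 0.05).
#' @return data.frame with columns `center` (Angstrom), `prob`, `prominence`,
#'   sorted by descending probability.
#' @export
find_peaks <- function(dist, min_prominence = 0.05) {
  stopifnot(inherits(dist, "distance_distribution"),
            min_prominence >= 0, min_prominence <= 1)
  p <- dist$prob
  B <- length(p)
  if (B == 1L) {
    out <- data.frame(center = dist$centers, prob = p, prominence = p)
    return(out[out$prominence >= min_prominence, , drop = FALSE])
  }
  # local maximum: >= both in-signal neighbours and strictly > at least one
  # (a perfectly flat run is not a peak)
  left <- c(-Inf, p[-B]); right <- c(p[-1], -Inf)
  is_peak <- which(p >= left & p >= right &
                     (p > c(Inf, p[-B]) | p > c(p[-1], Inf)))
  if (!length(is_peak))
    return(data.frame(center = numeric(0), prob = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(is_peak, function(i) {
    h <- p[i]
    # walk each way to the first strictly higher bin; the base is the lowest
    # bin en route, or the zero tail if the edge is reached first
    base_side <- function(step) {
      j <- i; mn <- h
      repeat {
        j <- j + step
        if (j < 1L || j > B) return(0)       # edge: histogram tail is zero
        if (p[j] > h) return(mn)
        mn <- min(mn, p[j])
      }
    }
    h - max(base_side(-1L), base_side(1L))
  }, 0)
  keep <- prom >= min_prominence & prom > 0
  out <- data.frame(center = dist$centers[is_peak][keep],
                    prob = p[is_peak][keep], prominence = prom[keep])
  out[order(out$prob, decreasing = TRUE), , drop = FALSE]
}

#' Write a distance distribution as two-column TSV
#' @param dist a `distance_distribution`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_distribution <- function(dist, path) {
  lines <- c("bin_center\tprobability",
             sprintf("%.6g\t%.8g", dist$centers, dist$prob))
  writeLines(lines, path)
  invisible(path)
}
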