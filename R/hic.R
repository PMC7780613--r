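#' Construct a binned Hi-C contact matrix
#'
#' @param counts symmetric non-negative numeric matrix.
#' @param bin_bp bin size in bp.
#' @param balanced has the matrix been ICE-balanced.
#' @param masked integer indices of masked (low-coverage) bins.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bin_bp, balanced = FALSE,
                           masked = integer()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contact matrix must be square")
  if (any(counts < 0)) stop("negative contact counts")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8))) {
    stop("contact matrix must be symmetric")
  }
  structure(list(counts = counts, n_bins = nrow(counts),
                 bin_bp = as.integer(bin_bp), balanced = balanced,
                 masked = as.integer(masked)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins x %d bp%s, %d masked\n", x$n_bins,
              x$bin_bp, if (x$balanced) " (balanced)" else "",
              length(x$masked)))
  invisible(x)
}

#' Read a binned contact matrix from triplet text
#'
#' Rows are `bin_i  bin_j  count` (1-based bins, whitespace-separated);
#' only one triangle need be present, the matrix is symmetrized. An empty
#' file yields a zero matrix.
#'
#' @param path triplet file.
#' @param bin_bp bin size in bp.
#' @param n_bins number of bins; default the largest index seen.
#' @return a `contact_matrix`.
#' @export
read_triplet <- function(path, bin_bp, n_bins = NULL) {
  d <- tryCatch(read.table(path, col.names = c("i", "j", "x")),
                error = function(e) data.frame(i = integer(), j = integer(),
                                               x = numeric()))
  if (nrow(d) && any(d$x < 0)) stop("negative contact counts in ", path)
  if (is.null(n_bins)) n_bins <- if (nrow(d)) max(d$i, d$j) else 0L
  if (nrow(d) && (any(d$i < 1L) || any(d$j < 1L) || max(d$i, d$j) > n_bins)) {
    stop("bin index out of range in ", path)
  }
  m <- matrix(0, n_bins, n_bins)
  if (nrow(d)) {
    m[cbind(d$i, d$j)] <- d$x
    m[cbind(d$j, d$i)] <- d$x
  }
  contact_matrix(m, bin_bp)
}

#' Write a contact matrix as triplet text (upper triangle incl. diagonal)
#' @param cm a `contact_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_triplet <- function(cm, path) {
  idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
               arr.ind = TRUE)
  d <- data.frame(i = idx[, 1L], j = idx[, 2L],
                  x = signif(cm$counts[idx], 10))
  d <- d[order(d$i, d$j), ]
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Square-root scaling variant: bins below the `filter_low_pct` coverage
#' percentile are masked, then rows and columns are repeatedly divided by
#' the square root of their marginal sums until all unmasked bin sums agree
#' to within `tol` (relative). The balanced matrix is rescaled so the mean
#' unmasked bin sum is 1.
#'
#' @param cm a `contact_matrix`.
#' @param filter_low_pct percentile (0-100) of bin coverage below which a
#'   bin is masked; zero-coverage bins are always masked.
#' @param tol convergence tolerance on relative bin-sum spread.
#' @param max_iter iteration cap.
#' @return a balanced `contact_matrix`.
#' @export
ice_balance <- function(cm, filter_low_pct = 2, tol = 1e-5, max_iter = 100L) {
  m <- cm$counts
  cov <- rowSums(m)
  thr <- stats::quantile(cov[cov > 0], filter_low_pct / 100, names = FALSE)
  masked <- which(cov == 0 | cov < thr)
  keep <- setdiff(seq_len(nrow(m)), masked)
  if (!length(keep)) stop("all bins masked; nothing to balance")
  sub <- m[keep, keep, drop = FALSE]
  for (it in seq_len(max_iter)) {
    s <- rowSums(sub)
    if (any(s == 0)) stop("zero marginal among unmasked bins")
    if (max(abs(s / mean(s) - 1)) < tol) break
    sq <- sqrt(s)
    sub <- sub / outer(sq, sq)
  }
  sub <- sub / mean(rowSums(sub))
  out <- matrix(0, nrow(m), ncol(m))
  out[keep, keep] <- sub
  contact_matrix(out, cm$bin_bp, balanced = TRUE, masked = masked)
}

#' Insulation-score segmentation into chromosomal interacting domains
#'
#' The insulation score of bin b is the mean contact count in the
#' `window_bins` x `window_bins` square of contacts straddling b (bins
#' b-w..b-1 against b+1..b+w). Boundaries are local minima of the log2
#' insulation profile whose prominence (rise to the nearest higher flank on
#' the weaker side) is at least `delta_threshold`; domains are the bin
#' intervals between consecutive boundaries.
#'
#' @param cm a balanced `contact_matrix` (a raw one is accepted: insulation
#'   is invariant to global scale, but unbalanced coverage will bias it).
#' @param window_bins half-window in bins (default 5, i.e. 10 kbp at 2-kbp
#'   bins, bracketing the 2-10 kbp scale of yeast CIDs).
#' @param delta_threshold minimum prominence in log2 units (default 0.1).
#' @return an object of class `cid_segmentation`: list with `boundaries`
#'   (bin index at which a new domain starts), `domains` (data.frame
#'   `start_bin`, `end_bin`, `start_bp`, `end_bp`), `insulation` (per-bin,
#'   NA where undefined), `bin_bp`.
#' @export
insulation_cids <- function(cm, window_bins = 5L, delta_threshold = 0.1) {
  n <- cm$n_bins
  w <- as.integer(window_bins)
  if (2L * w >= n) stop("window larger than the matrix")
  m <- cm$counts
  ins <- rep(NA_real_, n)
  for (b in (w + 1L):(n - w)) {
    ins[b] <- mean(m[(b - w):(b - 1L), (b + 1L):(b + w)])
  }
  li <- log2(ins + 1e-12)
  valid <- which(!is.na(ins))
  boundaries <- integer()
  for (b in valid) {
    if (b <= min(valid) || b >= max(valid)) next
    if (!(li[b] <= li[b - 1L] && li[b] < li[b + 1L])) next
    prom <- function(idx_seq) {
      best <- -Inf
      for (k in idx_seq) {
        if (is.na(li[k])) break
        if (li[k] < li[b]) break
        best <- max(best, li[k])
      }
      best - li[b]
    }
    p <- min(prom(rev(seq(min(valid), b - 1L))), prom(seq(b + 1L, max(valid))))
    if (is.finite(p) && p >= delta_threshold) boundaries <- c(boundaries, b)
  }
  # a minimum at bin b separates the domain ending at b from the one
  # starting at b+1
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  domains <- data.frame(start_bin = starts, end_bin = ends,
                        start_bp = (starts - 1L) * cm$bin_bp,
                        end_bp = ends * cm$bin_bp)
  structure(list(boundaries = boundaries, domains = domains,
                 insulation = ins, bin_bp = cm$bin_bp),
            class = "cid_segmentation")
}

#' @export
print.cid_segmentation <- function(x, ...) {
  cat(sprintf("cid_segmentation: %d domains (%d boundaries), bin %d bp\n",
              nrow(x$domains), length(x$boundaries), x$bin_bp))
  invisible(x)
}

#' Domain index of genomic positions
#' @param cids a `cid_segmentation`.
#' @param pos_bp positions in bp.
#' @return integer domain indices.
#' @export
cid_of_position <- function(cids, pos_bp) {
  findInterval(pos_bp, c(0, cids$domains$end_bp[-nrow(cids$domains)], Inf))
}

#' Default parameters of the proximity weight models
#'
#' `alpha` is the distance-decay exponent, `d0` a short-range offset in bp,
#' `beta` the same-CID contact boost. The defaults are calibrated once so
#' that the default simulation conditions reproduce the observed scale of
#' selected deletion segments (median around 7 kbp); see the methods
#' vignette.
#' @return list with `alpha`, `d0`, `beta`.
#' @export
default_weight_params <- function() list(alpha = 1.34, d0 = 500, beta = 3)

#' Recombination weights over the current loxPsym sites of a strain
#'
#' Three models for the relative propensity of a site pair to synapse:
#' \describe{
#'   \item{power_law}{`w = (d + d0)^(-alpha)` with `d` the current linear
#'     separation in bp (sum of intervening segment lengths plus interior
#'     loxPsym sites).}
#'   \item{hic_contact}{`w` = balanced contact count of the two sites'
#'     reference-origin bins. Valid for an unrearranged strain; after
#'     rearrangement the reference-origin lookup is an approximation.}
#'   \item{cid_boost}{power_law multiplied by `beta` when both sites map to
#'     the same chromosomal interacting domain (by reference origin).}
#' }
#'
#' @param state a `chromosome_state`.
#' @param model `"power_law"`, `"hic_contact"` or `"cid_boost"`.
#' @param params list with `alpha`, `d0` (bp), `beta`.
#' @param matrix `contact_matrix` (required for hic_contact).
#' @param cids `cid_segmentation` (required for cid_boost).
#' @return symmetric non-negative matrix over current site pairs, zero
#'   diagonal, class `proximity_weights` attributes recording the model.
#' @export
weights_for_sites <- function(state, model = c("power_law", "hic_contact", "cid_boost"),
                              params = default_weight_params(),
                              matrix = NULL, cids = NULL) {
  model <- match.arg(model)
  ns <- nrow(state$sites)
  pos <- state_site_positions(state)
  if (model == "hic_contact") {
    if (is.null(matrix)) stop("hic_contact weights need a contact matrix")
    ref <- reference_site_positions(state)
    bin <- pmin(ref %/% matrix$bin_bp + 1L, matrix$n_bins)
    w <- matrix$counts[bin, bin, drop = FALSE]
  } else {
    d <- abs(outer(pos, pos, "-"))
    w <- (d + params$d0)^(-params$alpha)
    if (model == "cid_boost") {
      if (is.null(cids)) stop("cid_boost weights need a CID segmentation")
      ref <- reference_site_positions(state)
      dom <- cid_of_position(cids, ref)
      same <- outer(dom, dom, "==")
      w[same] <- w[same] * params$beta
    }
  }
  diag(w) <- 0
  w <- (w + t(w)) / 2
  attr(w, "model") <- model
  attr(w, "params") <- params
  class(w) <- c("proximity_weights", class(w))
  w
}

#' Fraction of deleted segments falling entirely inside one CID
#'
#' A maximal contiguous deleted reference segment is concordant when its
#' interval lies within a single chromosomal interacting domain. Reported
#' over all deleted segments of all supplied profiles.
#'
#' @param profiles list of `lu_profile` objects (or one).
#' @param cids a `cid_segmentation` on reference coordinates.
#' @return fraction in [0, 1] (NaN when there are no deleted segments).
#' @export
deletion_cid_concordance <- function(profiles, cids) {
  if (inherits(profiles, "lu_profile")) profiles <- list(profiles)
  segs <- do.call(rbind, lapply(profiles, function(p) p$deleted_segments))
  if (is.null(segs) || !nrow(segs)) return(NaN)
  d1 <- cid_of_position(cids, segs$start_bp)
  d2 <- cid_of_position(cids, pmax(segs$end_bp - 1L, segs$start_bp))
  mean(d1 == d2)
}
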