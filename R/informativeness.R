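#' Variable and parsimony-informative site counts
#'
#' Per alignment column over the five states \code{A, C, G, T, -} (the gap
#' is a fifth state; \code{N} and IUPAC ambiguity codes are treated as
#' missing): a column is variable when at least two distinct states occur,
#' and parsimony-informative when at least two distinct states each occur
#' in at least two rows.
#'
#' @param aln a [multi_aln()] with at least two rows.
#' @return list with \code{n_sites}, \code{n_variable}, \code{n_pis},
#'   \code{pis_fraction}.
#' @export
count_sites <- function(aln) {
  m <- unclass(aln)
  if (nrow(m) < 2L) stopf("site statistics need at least two sequences")
  states <- c("A", "C", "G", "T", "-")
  counts <- vapply(states, function(s) colSums(m == s),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, states))
  n_state <- rowSums(counts > 0)
  n_state2 <- rowSums(counts >= 2)
  n_variable <- sum(n_state >= 2L)
  n_pis <- sum(n_state2 >= 2L)
  list(n_sites = ncol(m), n_variable = n_variable, n_pis = n_pis,
       pis_fraction = n_pis / ncol(m))
}

#' Remove gappy and poorly conserved alignment columns
#'
#' A light column filter standing in for heavier alignment-trimming tools:
#' a column is removed when its gap fraction exceeds \code{max_gap_frac} or
#' when the frequency of its modal unambiguous base among unambiguous
#' characters falls below \code{min_conservation}.  Row order is preserved
#' and the original indices of the kept columns are returned in the
#' \code{col_map} attribute so trimming is auditable.
#'
#' @param aln a [multi_aln()].
#' @param max_gap_frac maximum tolerated gap fraction per column.
#' @param min_conservation minimum modal-base frequency per column.
#' @return the trimmed [multi_aln()] with attribute \code{col_map}.
#' @export
clean_alignment <- function(aln, max_gap_frac = 0.5,
                            min_conservation = 0.5) {
  m <- unclass(aln)
  gap_frac <- colSums(m == "-") / nrow(m)
  base_counts <- vapply(c("A", "C", "G", "T"),
                        function(s) colSums(m == s), numeric(ncol(m)))
  if (ncol(m) == 1L) base_counts <- matrix(base_counts, nrow = 1L)
  n_base <- rowSums(base_counts)
  conserv <- ifelse(n_base > 0, apply(base_counts, 1L, max) / n_base, 0)
  keep <- gap_frac <= max_gap_frac & conserv >= min_conservation
  out <- multi_aln(m[, keep, drop = FALSE],
                   locus_id = attr(aln, "locus_id"))
  attr(out, "col_map") <- which(keep)
  out
}

#' Calibrate an ultrametric tree to a crown age
#'
#' Scales every branch length so that the crown (root-to-tip) height equals
#' \code{crown_age}; the topology is unchanged.
#'
#' @param tree rooted ultrametric \code{phylo} tree.
#' @param crown_age target crown age in My (default 30).
#' @param tol relative tolerance for the ultrametricity check.
#' @return the rescaled \code{phylo} tree with attribute \code{crown_age}.
#' @export
calibrate_chronogram <- function(tree, crown_age = 30, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  if (h <= 0) stopf("tree has zero height")
  if (max(depths) - min(depths) > tol * h)
    stopf("tree is not ultrametric (tip depth spread %.3g)",
          max(depths) - min(depths))
  tree$edge.length <- tree$edge.length * (crown_age / h)
  attr(tree, "crown_age") <- crown_age
  tree
}

# JC69 transition probability of observing the same / a different base
# after time t at rate lambda (lambda in expected substitutions/site/My)
.jc69_psame <- function(lambda, t) 0.25 + 0.75 * exp(-4 * lambda * t / 3)

# 4 x 4 JC69 transition matrix
.jc69_P <- function(lambda, t) {
  ps <- .jc69_psame(lambda, t)
  po <- (1 - ps) / 3
  m <- matrix(po, 4L, 4L)
  diag(m) <- ps
  m
}

# map an alignment character to a 4-vector conditional likelihood at a tip;
# gaps, N and ambiguity codes contribute uniform (missing) or partial sets
.tip_clv <- function(ch) {
  bases <- c("A", "C", "G", "T")
  v <- numeric(4L)
  if (ch %in% bases) {
    v[match(ch, bases)] <- 1
  } else if (ch %in% names(.IUPAC_SETS)) {
    v[match(.IUPAC_SETS[[ch]], bases)] <- 1
  } else {
    v[] <- 1                              # '-' or unknown: missing
  }
  v
}

#' Per-site substitution rates on a fixed chronogram
#'
#' For each alignment column, the substitution rate (in expected
#' substitutions per site per My) that maximizes the pruning-algorithm
#' likelihood under the JC69 model on the fixed, time-calibrated tree,
#' found by bounded one-dimensional (golden-section) search on
#' \code{[0, lambda_max]}.  Columns with fewer than two distinct observed
#' bases are invariant and receive rate 0.  Identical site patterns are
#' estimated once and shared.
#'
#' @param aln a [multi_aln()] whose taxa are a subset of the chronogram
#'   tips.
#' @param chron time-calibrated \code{phylo} tree (see
#'   [calibrate_chronogram()]).
#' @param lambda_max search upper bound (default 10 subst/site/My).
#' @param site_classes optional integer/character vector of length
#'   \code{ncol(aln)} assigning columns to rate classes: one rate is then
#'   estimated jointly per class (log-likelihoods summed over the class's
#'   columns) and assigned to each member column.  The default estimates
#'   one rate per column.
#' @return numeric vector of per-column rates.
#' @export
estimate_site_rates <- function(aln, chron, lambda_max = 10,
                                site_classes = NULL) {
  taxa <- rownames(aln)
  if (!all(taxa %in% chron$tip.label))
    stopf("alignment taxa missing from the chronogram: %s",
          paste(setdiff(taxa, chron$tip.label), collapse = ", "))
  if (is.null(site_classes)) site_classes <- seq_len(ncol(aln))
  stopifnot(length(site_classes) == ncol(aln))
  tree <- ape::keep.tip(chron, taxa)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]

  observed <- apply(m, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")]))
  })
  if (length(unique(m[m %in% c("A", "C", "G", "T")])) < 2L) {
    warning("fewer than two observed states in the whole alignment; ",
            "returning all-zero rates")
    return(numeric(ncol(m)))
  }

  tips_clv <- array(0, dim = c(4L, ntip, ncol(m)))
  for (i in seq_len(ntip)) for (j in seq_len(ncol(m)))
    tips_clv[, i, j] <- .tip_clv(m[i, j])

  # pruning log-likelihood of one column
  site_loglik <- function(lambda, site) {
    partial <- matrix(1, 4L, nnode)
    for (k in seq_len(nrow(edge))) {
      par <- edge[k, 1L]; chd <- edge[k, 2L]
      P <- .jc69_P(lambda, elen[k])
      child_clv <- if (chd <= ntip) tips_clv[, chd, site]
                   else partial[, chd]
      partial[, par] <- partial[, par] * as.vector(P %*% child_clv)
    }
    root <- edge[nrow(edge), 1L]
    lik <- sum(0.25 * partial[, root])
    if (lik <= 0) -Inf else log(lik)
  }

  pattern_key <- apply(m, 2L, paste, collapse = "")
  rates <- numeric(ncol(m))
  for (cls in split(seq_len(ncol(m)), site_classes)) {
    # joint estimation over the class, collapsing repeated patterns
    upat <- cls[!duplicated(pattern_key[cls])]
    wt <- as.vector(table(factor(pattern_key[cls],
                                 levels = pattern_key[upat])))
    if (all(observed[cls] < 2L)) {
      rates[cls] <- 0
      next
    }
    ll <- function(l) sum(wt * vapply(upat, function(j)
      site_loglik(l, j), numeric(1)))
    # the log-likelihood is numerically flat over most of [0, lambda_max],
    # so bracket the peak on a log-spaced grid before local refinement
    grid <- c(0, 10^seq(log10(1e-6), log10(lambda_max), length.out = 40L))
    gv <- vapply(grid, ll, numeric(1))
    k <- which.max(gv)
    lo <- grid[max(1L, k - 1L)]
    hi <- grid[min(length(grid), k + 1L)]
    opt <- stats::optimize(ll, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-10)
    r <- opt$maximum
    if (gv[k] > opt$objective) r <- grid[k]
    if (ll(0) >= max(gv[k], opt$objective)) r <- 0
    rates[cls] <- r
  }
  rates
}

#' Phylogenetic-informativeness profile
#'
#' Net phylogenetic informativeness evaluated on a time grid: each site of
#' rate \code{lambda} contributes the four-taxon asymptotic informativeness
#' \code{rho(t; lambda) = 16 lambda^2 t exp(-4 lambda t)}, and the profile
#' is the sum over sites.  A single-rate profile peaks at
#' \code{t = 1/(4 lambda)}; profiles are additive over sites.
#'
#' @param rates numeric vector of per-site rates (subst/site/My).
#' @param t_grid increasing time grid in My; default 1000 points over
#'   \code{(0, 30]}.
#' @return a \code{pi_profile}: list with \code{t}, \code{net_pi} and the
#'   source \code{rates}.
#' @export
pi_profile <- function(rates, t_grid = seq(30 / 1000, 30,
                                           length.out = 1000)) {
  stopifnot(all(is.finite(rates)), all(rates >= 0),
            all(diff(t_grid) > 0), all(t_grid > 0))
  net <- vapply(t_grid, function(t)
    sum(16 * rates^2 * t * exp(-4 * rates * t)), numeric(1))
  structure(list(t = t_grid, net_pi = net, rates = rates),
            class = "pi_profile")
}

#' @export
print.pi_profile <- function(x, ...) {
  cat(sprintf("pi_profile: %d sites, grid (%g, %g], peak %.4g at t = %.3g\n",
              length(x$rates), min(x$t), max(x$t), max(x$net_pi),
              x$t[which.max(x$net_pi)]))
  invisible(x)
}

#' Area under a phylogenetic-informativeness profile
#'
#' Trapezoidal integral of the net-PI curve over \code{[t_min, t_max]}.
#' Since net PI is exactly 0 at \code{t = 0}, a grid starting above 0 still
#' covers \code{t_min = 0} (the origin point is supplied analytically);
#' otherwise the grid must span the requested interval.
#'
#' @param profile a [pi_profile()].
#' @param t_min,t_max integration bounds in My (defaults 0 and 30).
#' @return the integral (net PI x My).
#' @export
area_under_profile <- function(profile, t_min = 0, t_max = 30) {
  t <- profile$t; y <- profile$net_pi
  if (t_min == 0 && min(t) > 0) {
    t <- c(0, t); y <- c(0, y)
  }
  if (min(t) > t_min || max(t) < t_max)
    stopf("profile grid [%g, %g] does not span [%g, %g]",
          min(t), max(t), t_min, t_max)
  keep <- t >= t_min & t <= t_max
  tt <- t[keep]; yy <- y[keep]
  # linear interpolation at the exact bounds if the grid skips them
  if (tt[1L] > t_min) {
    y0 <- stats::approx(t, y, xout = t_min)$y
    tt <- c(t_min, tt); yy <- c(y0, yy)
  }
  if (tt[length(tt)] < t_max) {
    y1 <- stats::approx(t, y, xout = t_max)$y
    tt <- c(tt, t_max); yy <- c(yy, y1)
  }
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

# indices of strict interior local maxima of a series
.interior_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[y[i] > y[i - 1L] & y[i] > y[i + 1L]]
}

# elbow of a descending-sorted curve: index of the point with maximum
# perpendicular distance to the chord joining the first and last points,
# with both axes normalized to [0, 1]
.elbow_index <- function(sorted_desc) {
  m <- length(sorted_desc)
  if (m < 3L) return(1L)
  x <- (seq_len(m) - 1) / (m - 1)
  rng <- max(sorted_desc) - min(sorted_desc)
  y <- if (rng > 0) (sorted_desc - min(sorted_desc)) / rng
       else rep(0, m)
  # chord from (0, y1) to (1, ym)
  dx <- 1; dy <- y[m] - y[1L]
  d <- abs(dy * x - dx * (y - y[1L])) / sqrt(dx^2 + dy^2)
  which.max(d)
}

#' Remove phantom spikes from a PI profile
#'
#' Badly estimated fast sites inflate a profile with a spurious extra peak
#' near the origin.  A profile is flagged when it has more than one strict
#' interior local maximum on its grid.  For flagged profiles the per-site
#' rates are sorted in descending order, the elbow of the sorted-rate curve
#' is located (maximum perpendicular distance to the chord between its
#' endpoints, axes normalized), sites with rates strictly above the elbow
#' rate are discarded, and the profile is recomputed; this elbow-trim step
#' is applied exactly twice.  Unflagged profiles are returned unchanged.
#'
#' @param profile a [pi_profile()].
#' @param aln optional [multi_aln()] with one column per profile site; if
#'   supplied, the trimmed alignment is returned alongside.
#' @return list with \code{profile} (cleaned), \code{removed_sites}
#'   (indices into the original rate vector), \code{flagged} (logical) and,
#'   when \code{aln} was given, \code{aln} (trimmed).
#' @export
remove_phantom_spikes <- function(profile, aln = NULL) {
  if (!is.null(aln) && ncol(aln) != length(profile$rates))
    stopf("alignment has %d columns but the profile has %d sites",
          ncol(aln), length(profile$rates))
  flagged <- length(.interior_maxima(profile$net_pi)) > 1L
  if (!flagged)
    return(list(profile = profile, removed_sites = integer(0),
                flagged = FALSE, aln = aln))
  keep <- seq_along(profile$rates)
  for (pass in 1:2) {
    r <- profile$rates[keep]
    o <- order(r, decreasing = TRUE)
    thr <- r[o][.elbow_index(r[o])]
    keep <- keep[r <= thr]
  }
  removed <- setdiff(seq_along(profile$rates), keep)
  cleaned <- pi_profile(profile$rates[keep], t_grid = profile$t)
  out <- list(profile = cleaned, removed_sites = removed, flagged = TRUE)
  out$aln <- if (!is.null(aln) && length(keep) > 0L)
    multi_aln(unclass(aln)[, keep, drop = FALSE],
              locus_id = attr(aln, "locus_id"))
  else aln
  out
}

#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors of equal length, at least 3 points.
#' @return list with \code{slope}, \code{intercept} and \code{r_squared}.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stopf("x has zero variance")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}
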