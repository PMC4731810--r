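#' Weber fractions from relative cone abundances
#'
#' Receptor noise in the receptor-noise-limited colour discrimination model
#' scales with the number of cones pooled per channel: the Weber fraction of
#' receptor i is `base_noise * sqrt(max_abundance / abundance_i)`, so the most
#' abundant cone class has the base noise-to-signal ratio (default 0.05) and
#' rarer classes are noisier.
#'
#' @param cone_ratio positive relative abundances, shortest to longest
#'   wavelength (e.g. ferret 1:14, human 1:5.49:10.99, peafowl 1:1.9:2.2:2.1).
#' @param base_noise noise-to-signal ratio of the most abundant cone.
#' @return named numeric vector of Weber fractions.
#' @examples
#' weber_fractions(c(1, 14))            # ferret: 0.1871, 0.0500
#' weber_fractions(c(1, 5.49, 10.99))   # human
#' @export
weber_fractions <- function(cone_ratio, base_noise = 0.05) {
  if (any(cone_ratio <= 0)) stop("cone abundances must be positive")
  base_noise * sqrt(max(cone_ratio) / cone_ratio)
}

# receptor-noise distance from a matrix of log-catch differences (rows)
jnd_from_df <- function(df, w) {
  n <- length(w)
  if (is.null(dim(df))) df <- matrix(df, ncol = n)
  if (n == 2L) {
    abs(df[, 1] - df[, 2]) / sqrt(w[1]^2 + w[2]^2)
  } else if (n == 3L) {
    num <- w[1]^2 * (df[, 2] - df[, 3])^2 +
           w[2]^2 * (df[, 1] - df[, 3])^2 +
           w[3]^2 * (df[, 1] - df[, 2])^2
    den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
    sqrt(num / den)
  } else if (n == 4L) {
    num <- (w[1] * w[2])^2 * (df[, 4] - df[, 3])^2 +
           (w[1] * w[3])^2 * (df[, 4] - df[, 2])^2 +
           (w[1] * w[4])^2 * (df[, 3] - df[, 2])^2 +
           (w[2] * w[3])^2 * (df[, 4] - df[, 1])^2 +
           (w[2] * w[4])^2 * (df[, 3] - df[, 1])^2 +
           (w[3] * w[4])^2 * (df[, 2] - df[, 1])^2
    den <- (w[1] * w[2] * w[3])^2 + (w[1] * w[2] * w[4])^2 +
           (w[1] * w[3] * w[4])^2 + (w[2] * w[3] * w[4])^2
    sqrt(num / den)
  } else {
    stop("receptor-noise distance implemented for 2, 3 or 4 receptors")
  }
}

#' Receptor-noise colour distance (just noticeable differences)
#'
#' Colour distance between two cone-catch points under the receptor-noise
#' limited model. Catch ratios enter on a log scale (Weber-Fechner form),
#' `df_i = ln(catch_a_i / catch_b_i)`, and the channel differences are
#' combined in the standard quadratic forms for 2, 3 or 4 receptors with the
#' Weber fractions as channel noise. A distance of ~1 JND is at the
#' discrimination threshold under ideal viewing.
#'
#' @param catch_a,catch_b positive per-receptor quantum catches of the two
#'   colours (equal length, 2-4 receptors).
#' @param weber Weber fractions, same receptor order.
#' @return non-negative scalar distance in JND.
#' @export
jnd_distance <- function(catch_a, catch_b, weber) {
  if (length(catch_a) != length(catch_b) || length(catch_a) != length(weber))
    stop("catch vectors and Weber fractions must have equal length")
  if (any(catch_a <= 0) || any(catch_b <= 0))
    stop("quantum catches must be positive (clamp upstream)")
  jnd_from_df(log(catch_a) - log(catch_b), weber)
}

#' Cluster a region into its dominant colours
#'
#' Two-pass perceptual clustering of the cone-catch pixels in a region.
#' Pass 1 (local): scanning row-major from the top-left, each unassigned pixel
#' seeds a cluster that grows by 4-connectivity, absorbing neighbours whose
#' colour is within `local_thresh` JND of the pixel they adjoin (so smooth
#' colour gradients chain into a single colour; set `local_compare = "mean"`
#' to compare against the cluster's running mean instead, which splits long
#' gradients). Pass 2 (global):
#' processing clusters largest first, each absorbs any other cluster whose
#' mean is within `global_thresh` JND of its own (running) mean. Clusters are
#' reported in decreasing coverage order until cumulative coverage reaches
#' `coverage_stop` or `max_colours` clusters.
#'
#' @param cone cone-catch image ([apply_mapping()]) or `h x w x n` array;
#'   clustering uses the chromatic receptor channels named by `weber`.
#' @param mask logical region mask.
#' @param weber named Weber fractions (names select + order the channels; an
#'   unnamed vector uses the first `length(weber)` channels).
#' @param local_thresh JND threshold for adjacent-pixel merging (0.05).
#' @param global_thresh JND threshold for cluster linking (1).
#' @param max_colours stop after this many colours (32).
#' @param coverage_stop stop once this fraction of the region is covered
#'   (0.99).
#' @param local_compare what an adjoining pixel is compared against during
#'   growth: the neighbouring pixel itself (default) or the cluster running
#'   mean.
#' @return data.frame of class `colour_clusters`: one row per colour with
#'   `coverage`, `n_pixels` and mean catch per receptor, sorted by coverage
#'   (ties broken by discovery order).
#' @export
cluster_colours <- function(cone, mask, weber, local_thresh = 0.05,
                            global_thresh = 1, max_colours = 32L,
                            coverage_stop = 0.99,
                            local_compare = c("neighbour", "mean")) {
  local_compare <- match.arg(local_compare)
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  chans <- dimnames(cone)[[3]]
  sel <- if (!is.null(names(weber)) && all(names(weber) %in% chans))
    names(weber) else seq_along(weber)
  nrec <- length(weber)
  d <- dim(cone)
  catches <- matrix(cone[, , sel], d[1] * d[2], nrec)
  nr <- d[1]; nc <- d[2]
  lab <- integer(nr * nc)            # 0 = unassigned / outside mask
  inmask <- as.vector(mask)
  # row-major scan order over masked pixels
  idx_all <- which(inmask)
  ord <- order((idx_all - 1L) %% nr, (idx_all - 1L) %/% nr)
  scan <- idx_all[ord]
  means <- list(); sizes <- integer(0)
  nbr_off <- c(-1L, 1L, -nr, nr)     # up, down, left, right
  for (seed in scan) {
    if (lab[seed] != 0L) next
    cl <- length(sizes) + 1L
    lab[seed] <- cl
    m <- catches[seed, ]
    k <- 1L
    queue <- seed
    head <- 1L
    while (head <= length(queue)) {
      p <- queue[head]; head <- head + 1L
      row <- (p - 1L) %% nr + 1L
      for (o in nbr_off) {
        q <- p + o
        if (o == -1L && row == 1L) next
        if (o == 1L && row == nr) next
        if (q < 1L || q > nr * nc) next
        if (!inmask[q] || lab[q] != 0L) next
        ref <- if (local_compare == "neighbour") catches[p, ] else m
        dfv <- log(catches[q, ]) - log(ref)
        if (jnd_from_df(dfv, weber) <= local_thresh) {
          lab[q] <- cl
          m <- (m * k + catches[q, ]) / (k + 1L)
          k <- k + 1L
          queue[length(queue) + 1L] <- q
        }
      }
    }
    means[[cl]] <- m
    sizes[cl] <- k
  }
  # global linking, largest cluster first
  alive <- rep(TRUE, length(sizes))
  for (i in order(-sizes)) {
    if (!alive[i]) next
    repeat {
      others <- which(alive & seq_along(sizes) != i & sizes > 0)
      if (!length(others)) break
      dm <- t(vapply(others, function(j) log(means[[j]]) - log(means[[i]]),
                     numeric(length(weber))))
      near <- others[jnd_from_df(dm, weber) <= global_thresh]
      if (!length(near)) break
      for (j in near) {
        means[[i]] <- (means[[i]] * sizes[i] + means[[j]] * sizes[j]) /
          (sizes[i] + sizes[j])
        sizes[i] <- sizes[i] + sizes[j]
        alive[j] <- FALSE
      }
    }
  }
  keep <- which(alive)
  total <- sum(sizes[keep])
  # stable sort: coverage descending, earlier discovery wins ties
  keep <- keep[order(-sizes[keep], keep)]
  cum <- cumsum(sizes[keep]) / total
  n_stop <- if (any(cum >= coverage_stop)) which(cum >= coverage_stop)[1] else length(keep)
  n_report <- min(length(keep), max_colours, n_stop)
  keep <- keep[seq_len(n_report)]
  out <- data.frame(cluster = seq_along(keep),
                    coverage = sizes[keep] / total,
                    n_pixels = sizes[keep])
  catch_mat <- do.call(rbind, means[keep])
  colnames(catch_mat) <- if (is.character(sel)) sel else paste0("catch_", sel)
  out <- cbind(out, catch_mat)
  class(out) <- c("colour_clusters", "data.frame")
  out
}

#' Best and coverage-weighted mean colour match
#'
#' How well the single most abundant target colour (the main egg or plumage
#' colour) matches the colours of the surrounds: `best_jnd` is its distance to
#' the closest background colour; `mean_jnd` is its coverage-weighted mean
#' distance to all background colours (weights renormalized over the reported
#' clusters).
#'
#' @param target_clusters,background_clusters [cluster_colours()] results.
#' @param weber Weber fractions used for the clustering.
#' @return list with `best_jnd` and `mean_jnd` (`best_jnd <= mean_jnd`).
#' @export
colour_match_metrics <- function(target_clusters, background_clusters, weber) {
  if (!nrow(target_clusters) || !nrow(background_clusters))
    stop("empty cluster list")
  ncol_meta <- 3L
  tc <- as.numeric(target_clusters[1, -(seq_len(ncol_meta))])
  bg <- as.matrix(background_clusters[, -(seq_len(ncol_meta)), drop = FALSE])
  dm <- sweep(log(bg), 2, log(tc))
  jnds <- jnd_from_df(dm, weber)
  wts <- background_clusters$coverage
  list(best_jnd = min(jnds),
       mean_jnd = sum(wts * jnds) / sum(wts))
}
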