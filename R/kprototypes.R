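# Mixed-type clustering for eco-functional cluster delineation. The
# dissimilarity between an observation and a prototype is the sum of squared
# differences over z-standardized continuous fields plus lambda times the
# count of categorical mismatches.

as_mixed_frame <- function(data, numeric_cols = NULL, cat_cols = NULL) {
  df <- as.data.frame(data)
  if (is.null(numeric_cols)) {
    numeric_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  if (is.null(cat_cols)) {
    cat_cols <- setdiff(names(df), numeric_cols)
  }
  list(
    num = as.matrix(df[numeric_cols]),
    cat = if (length(cat_cols)) {
      m <- df[cat_cols]
      m[] <- lapply(m, as.character)
      as.matrix(m)
    } else NULL,
    numeric_cols = numeric_cols, cat_cols = cat_cols
  )
}

# n x k matrix of mixed dissimilarities to prototypes, on standardized scale
mixed_dist_matrix <- function(znum, catm, proto_num, proto_cat, lambda) {
  k <- nrow(proto_num)
  n <- nrow(znum)
  d <- matrix(0, n, k)
  for (j in seq_len(k)) {
    dn <- rowSums(sweep(znum, 2, proto_num[j, ], "-")^2)
    dc <- 0
    if (!is.null(catm)) {
      dc <- rowSums(catm != matrix(proto_cat[j, ], n, ncol(catm), byrow = TRUE))
    }
    d[, j] <- dn + lambda * dc
  }
  d
}

col_modes <- function(m) {
  apply(m, 2, function(x) names(which.max(table(x))))
}

#' Fit a k-prototypes clustering model
#'
#' Alternating assignment/update minimisation of the mixed dissimilarity
#' \eqn{d(x, p) = \sum_j (z_j - p_j)^2 + \lambda \cdot \#\{c : x_c \neq
#' p_c\}} where continuous fields are z-standardized and categorical fields
#' count mismatches. Prototypes are per-cluster means (continuous) and modes
#' (categorical). Assignment ties break to the lowest cluster index; empty
#' clusters are re-seeded from the point farthest from its prototype.
#'
#' @param data Data frame of observations; numeric columns are treated as
#'   continuous, everything else as categorical (override with
#'   `numeric_cols` / `cat_cols`).
#' @param k Number of clusters.
#' @param lambda Categorical mixing weight; `NULL` (default) uses half the
#'   mean variance of the standardized continuous fields (i.e. 0.5).
#' @param seed Integer seed for the initialisation (k distinct observations).
#' @param max_iter Maximum alternating iterations.
#' @param numeric_cols,cat_cols Optional explicit column roles.
#' @param init Optional integer vector of `k` row indices to initialise from.
#' @param n_start Number of random restarts (best objective kept), default 5;
#'   ignored when `init` is supplied.
#' @return A `kprototypes` object: `cluster` (assignments), `centers`
#'   (standardized numeric prototypes), `centers_cat`, `lambda`, `scale`
#'   (per-field mean/SD), `iterations`, `tot_within` (objective).
#' @export
fit_kprototypes <- function(data, k, lambda = NULL, seed = 1L,
                            max_iter = 100L, numeric_cols = NULL,
                            cat_cols = NULL, init = NULL, n_start = 5L) {
  mf <- as_mixed_frame(data, numeric_cols, cat_cols)
  n <- nrow(mf$num)
  if (ncol(mf$num) < 1) stop("at least one continuous field is required")
  if (n <= k) stop("need more observations than clusters (n > k)")

  mu <- colMeans(mf$num)
  sdev <- apply(mf$num, 2, sd)
  if (any(sdev == 0)) sdev[sdev == 0] <- 1
  znum <- sweep(sweep(mf$num, 2, mu, "-"), 2, sdev, "/")
  if (is.null(lambda)) lambda <- mean(apply(znum, 2, var)) / 2
  stopifnot(lambda >= 0)

  key <- apply(cbind(znum, mf$cat), 1, paste, collapse = "\r")
  if (length(unique(key)) < k) {
    stop("fewer distinct observations than clusters")
  }

  run_once <- function(init_idx) {
    proto_num <- znum[init_idx, , drop = FALSE]
    proto_cat <- if (!is.null(mf$cat)) mf$cat[init_idx, , drop = FALSE] else NULL
    assign_old <- rep(0L, n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d <- mixed_dist_matrix(znum, mf$cat, proto_num, proto_cat, lambda)
      assign_new <- max.col(-d, ties.method = "first")
      # re-seed empty clusters from the farthest point
      for (j in seq_len(k)) {
        if (!any(assign_new == j)) {
          far <- which.max(d[cbind(seq_len(n), assign_new)])
          assign_new[far] <- j
          d[far, ] <- Inf
        }
      }
      for (j in seq_len(k)) {
        idx <- assign_new == j
        proto_num[j, ] <- colMeans(znum[idx, , drop = FALSE])
        if (!is.null(mf$cat)) {
          proto_cat[j, ] <- col_modes(mf$cat[idx, , drop = FALSE])
        }
      }
      if (all(assign_new == assign_old) || iter >= max_iter) break
      assign_old <- assign_new
    }
    d <- mixed_dist_matrix(znum, mf$cat, proto_num, proto_cat, lambda)
    list(cluster = assign_new, centers = proto_num, centers_cat = proto_cat,
         iterations = iter,
         tot_within = sum(d[cbind(seq_len(n), assign_new)]))
  }

  set.seed(seed)
  inits <- if (!is.null(init)) list(init) else
    lapply(seq_len(n_start), function(s) {
      ord <- sample.int(n)
      ord[!duplicated(key[ord])][seq_len(k)]
    })
  best <- NULL
  for (ini in inits) {
    res <- run_once(ini)
    if (is.null(best) || res$tot_within < best$tot_within) best <- res
  }

  structure(list(
    cluster = best$cluster, k = k, centers = best$centers,
    centers_cat = best$centers_cat, lambda = lambda,
    scale = list(mean = mu, sd = sdev),
    numeric_cols = mf$numeric_cols, cat_cols = mf$cat_cols,
    iterations = best$iterations, tot_within = best$tot_within, seed = seed
  ), class = "kprototypes")
}

#' @export
print.kprototypes <- function(x, ...) {
  cat(sprintf("<kprototypes> k = %d, lambda = %.3g, %d iterations, objective %.4g\n",
              x$k, x$lambda, x$iterations, x$tot_within))
  cat("  sizes:", paste(tabulate(x$cluster, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_kprototypes
#' @param x A `kprototypes` object.
#' @param ... Unused.
#' @export
tidy.kprototypes <- function(x, ...) {
  ctr <- sweep(sweep(x$centers, 2, x$scale$sd, "*"), 2, x$scale$mean, "+")
  out <- tibble::as_tibble(as.data.frame(ctr))
  names(out) <- x$numeric_cols
  out <- dplyr::bind_cols(tibble::tibble(cluster = seq_len(x$k),
                                         size = tabulate(x$cluster, x$k)), out)
  if (!is.null(x$centers_cat)) {
    cats <- tibble::as_tibble(as.data.frame(x$centers_cat,
                                            stringsAsFactors = FALSE))
    names(cats) <- x$cat_cols
    out <- dplyr::bind_cols(out, cats)
  }
  out
}

#' @rdname fit_kprototypes
#' @export
glance.kprototypes <- function(x, ...) {
  tibble::tibble(k = x$k, lambda = x$lambda, tot_within = x$tot_within,
                 iterations = x$iterations, n = length(x$cluster))
}

# full pairwise mixed dissimilarity (standardized), for silhouettes
mixed_pairwise_dist <- function(znum, catm, lambda) {
  d <- as.matrix(stats::dist(znum))^2
  if (!is.null(catm)) {
    for (j in seq_len(ncol(catm))) {
      d <- d + lambda * outer(catm[, j], catm[, j], "!=")
    }
  }
  d
}

#' Mean silhouette of a partition under the mixed dissimilarity
#'
#' @param data Data frame of observations.
#' @param cluster Integer cluster assignments.
#' @param lambda Categorical mixing weight (`NULL` for the default
#'   heuristic).
#' @param numeric_cols,cat_cols Optional explicit column roles.
#' @return List with `mean` silhouette and per-observation widths `s`.
#' @export
silhouette_mixed <- function(data, cluster, lambda = NULL,
                             numeric_cols = NULL, cat_cols = NULL) {
  mf <- as_mixed_frame(data, numeric_cols, cat_cols)
  mu <- colMeans(mf$num); sdev <- apply(mf$num, 2, sd)
  sdev[sdev == 0] <- 1
  znum <- sweep(sweep(mf$num, 2, mu, "-"), 2, sdev, "/")
  if (is.null(lambda)) lambda <- mean(apply(znum, 2, var)) / 2
  d <- mixed_pairwise_dist(znum, mf$cat, lambda)
  n <- nrow(d)
  ks <- sort(unique(cluster))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    ni <- sum(own)
    a <- if (ni > 1) sum(d[i, own]) / (ni - 1) else 0
    b <- min(vapply(ks[ks != cluster[i]], function(j)
      mean(d[i, cluster == j]), numeric(1)))
    s[i] <- if (ni > 1) (b - a) / max(a, b) else 0
  }
  list(mean = mean(s), s = s)
}

#' Select the number of clusters by repeated-subsample silhouettes
#'
#' For each repetition, subsample `draw_size` observations, fit every `k` in
#' `k_range`, and score the partition by its mean silhouette under the mixed
#' dissimilarity; the chosen `k` maximises the repetition-averaged
#' silhouette. Defaults mirror an operational protocol of 30 repetitions of
#' 10,000 draws.
#'
#' @param data Data frame of observations.
#' @param k_range Candidate cluster counts (within `[2, n - 1]`).
#' @param reps Number of repetitions (default 30).
#' @param draw_size Subsample size per repetition (default 10000; must not
#'   exceed `nrow(data)`).
#' @param lambda,numeric_cols,cat_cols Passed to [fit_kprototypes()].
#' @param seed Integer seed.
#' @return List with `k` (chosen), `profile` (tibble of per-k mean
#'   silhouettes), `by_rep` (rep x k matrix).
#' @export
select_k <- function(data, k_range = 2:6, reps = 30, draw_size = 10000,
                     lambda = NULL, numeric_cols = NULL, cat_cols = NULL,
                     seed = 1L) {
  n <- nrow(data)
  if (draw_size > n) stop("draw_size exceeds the number of observations")
  stopifnot(reps >= 1, all(k_range >= 2), all(k_range <= n - 1))
  set.seed(seed)
  scores <- matrix(NA_real_, reps, length(k_range),
                   dimnames = list(NULL, paste0("k", k_range)))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, draw_size)
    sub <- data[idx, , drop = FALSE]
    for (j in seq_along(k_range)) {
      fit <- fit_kprototypes(sub, k_range[j], lambda = lambda,
                             seed = seed + r,
                             numeric_cols = numeric_cols, cat_cols = cat_cols)
      scores[r, j] <- silhouette_mixed(sub, fit$cluster, lambda = fit$lambda,
                                       numeric_cols = numeric_cols,
                                       cat_cols = cat_cols)$mean
    }
  }
  prof <- tibble::tibble(k = k_range, silhouette = colMeans(scores))
  list(k = k_range[which.max(prof$silhouette)], profile = prof,
       by_rep = scores)
}
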