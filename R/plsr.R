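#' Fit a PLSR model by NIPALS
#'
#' Partial least squares regression relating signalling features to
#' phenotypic responses. Columns of `X` and `Y` are centred and scaled to
#' unit variance, then latent components are extracted with the NIPALS
#' algorithm (weights `w`, scores `t = X w`, X-loadings `p`, Y-loadings
#' `q`, with deflation of both blocks after each component). The sign of
#' each weight vector is fixed so its first nonzero element is positive,
#' making fits reproducible and comparable across implementations.
#'
#' @param X Numeric condition x feature matrix (no missing values).
#' @param Y Numeric condition x response matrix or vector.
#' @param n_components Number of latent components,
#'   `<= min(nrow(X), ncol(X))` (default 2).
#' @param max_iter,tol NIPALS iteration controls.
#' @return A `plsr_model`: list with `weights` (p x a), `scores` (n x a),
#'   `x_loadings`, `y_loadings`, `explained_y_variance` (fraction of
#'   scaled-Y sum of squares per component), the centring/scaling vectors,
#'   and `feature_names`.
#' @export
fit_plsr <- function(X, Y, n_components = 2, max_iter = 500, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), !anyNA(X), !anyNA(Y))
  if (n_components > min(nrow(X), ncol(X)))
    stop("n_components exceeds min(rows, columns) of X")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  x_center <- colMeans(X); x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale == 0))
    stop("constant feature column(s) cannot be scaled: ",
         paste(colnames(X)[x_scale == 0], collapse = ", "))
  y_center <- colMeans(Y); y_scale <- apply(Y, 2, stats::sd)
  if (any(y_scale == 0))
    stop("constant response column(s) cannot be scaled")
  Xc <- scale(X, x_center, x_scale)
  Yc <- scale(Y, y_center, y_scale)
  ss_y_total <- sum(Yc^2)
  p <- ncol(X)
  W <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  expl <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2)), drop = TRUE]
    t_old <- rep(Inf, nrow(X))
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      w <- w / sqrt(sum(w^2))
      t_ <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, t_)) / sum(t_^2)
      u <- drop(Yc %*% q) / sum(q^2)
      if (sum((t_ - t_old)^2) / max(sum(t_^2), .Machine$double.eps) < tol)
        break
      t_old <- t_
    }
    # deterministic sign: first nonzero weight element positive
    nz <- which(abs(w) > 1e-12)[1]
    if (!is.na(nz) && w[nz] < 0) {
      w <- -w; t_ <- -t_; q <- -q
    }
    p_load <- drop(crossprod(Xc, t_)) / sum(t_^2)
    expl[a] <- sum(t_^2) * sum(q^2) / ss_y_total
    Xc <- Xc - tcrossprod(t_, p_load)
    Yc <- Yc - tcrossprod(t_, q)
    W[, a] <- w; Tm[, a] <- t_; P[, a] <- p_load; Q[, a] <- q
  }
  structure(list(n_components = n_components, weights = W, scores = Tm,
                 x_loadings = P, y_loadings = Q,
                 explained_y_variance = expl,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 feature_names = colnames(X)),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("<plsr_model> ", x$n_components, " component(s), ",
      length(x$feature_names), " features; explained Y variance: ",
      paste(format(x$explained_y_variance, digits = 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)`, where
#' `p` is the number of features and `SSY_a` the Y-variance explained by
#' component `a`. By construction the mean squared VIP is 1, so features
#' with VIP above 1 contribute more than average to predicting the
#' response (the conventional importance threshold; below 0.5 is
#' conventionally unimportant).
#'
#' @param model A fitted [fit_plsr()] model.
#' @return Named non-negative vector of VIP scores, one per feature.
#' @export
vip_scores <- function(model) {
  ssy <- model$explained_y_variance
  if (sum(ssy) <= 0) stop("model explains no Y variance; VIP undefined")
  W <- model$weights
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  vip <- sqrt(p * drop(wn2 %*% ssy) / sum(ssy))
  names(vip) <- model$feature_names
  vip
}

#' Simulate a panel of perturbed conditions
#'
#' Generates `n_conditions` simulations of a network, each with per-node
#' initial concentrations drawn from Uniform(`multiplier_range`) — a
#' synthetic stand-in for distinct treatments/replicates that vary the
#' input state while the topology and rates stay fixed.
#'
#' @param net A [signaling_network()].
#' @param rm Rate matrix for `net`.
#' @param n_conditions Number of conditions (default 30).
#' @param multiplier_range Bounds of the initial-concentration factors
#'   (default `c(0.5, 1.5)`).
#' @param seed Integer seed.
#' @param time_points Simulation grid (default `0:7`).
#' @return List with `series` (list of `time_series_set`) and
#'   `multipliers` (condition x node matrix).
#' @export
simulate_conditions <- function(net, rm, n_conditions = 30,
                                multiplier_range = c(0.5, 1.5), seed,
                                time_points = 0:7) {
  n <- length(net$node_names)
  mult <- withr::with_seed(seed,
    matrix(stats::runif(n_conditions * n, multiplier_range[1],
                        multiplier_range[2]),
           n_conditions, n, dimnames = list(NULL, net$node_names)))
  series <- lapply(seq_len(n_conditions), function(i)
    simulate_network(net, rm, x0 = mult[i, ], time_points = time_points))
  list(series = series, multipliers = mult)
}

#' Assemble a PLSR design from simulated conditions
#'
#' One row per condition; features are each non-read-out protein's series
#' flattened over time (columns `Node.t<k>`); the response is the read-out
#' level at the final time point.
#'
#' @param series List of `time_series_set`s over a common node set and
#'   grid (e.g. from [simulate_conditions()]).
#' @param readout_node Read-out species (default "Apop").
#' @return List with `X` (condition x feature matrix), `Y` (response
#'   vector) and `feature_nodes` (the node each column belongs to).
#' @export
assemble_plsr_data <- function(series, readout_node = "Apop") {
  stopifnot(length(series) >= 2)
  nodes <- setdiff(series[[1]]$node_names, readout_node)
  times <- series[[1]]$time_points
  X <- t(vapply(series, function(ts)
    as.vector(ts$values[, nodes]), numeric(length(nodes) * length(times))))
  feature_nodes <- rep(nodes, each = length(times))
  colnames(X) <- paste0(feature_nodes, ".t", rep(times, length(nodes)))
  Y <- vapply(series, function(ts)
    ts$values[length(times), readout_node], numeric(1))
  list(X = X, Y = Y, feature_nodes = feature_nodes)
}

#' Aggregate feature VIPs to node level
#'
#' @param vip Named VIP vector from [vip_scores()].
#' @param feature_nodes Node assignment per feature (from
#'   [assemble_plsr_data()]).
#' @return Named vector of mean VIP per node, sorted decreasingly.
#' @export
vip_by_node <- function(vip, feature_nodes) {
  agg <- tapply(vip, feature_nodes, mean)
  sort(agg, decreasing = TRUE)
}
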