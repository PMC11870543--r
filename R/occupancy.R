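# Occupancy classification, spectra, family segregation filters, and
# core-genome growth extrapolation over genome-order permutations.

#' Occupancy classification policy
#'
#' Thresholds generalize the four classes to arbitrary genome counts:
#' core = all n genomes; softcore = at least floor(0.95 n) but fewer than n;
#' cloud = 1 or 2; shell = everything in between.
#'
#' @param n_genomes Number of input genomes.
#' @param softcore_fraction Fraction defining the softcore threshold
#'   (default 0.95; the threshold is floor(fraction * n), reproducing
#'   15 of 16).
#' @param cloud_max Maximum occupancy of the cloud class (default 2).
#' @return list of class \code{occupancy_policy}.
#' @export
occupancy_policy <- function(n_genomes, softcore_fraction = 0.95, cloud_max = 2L) {
  stopifnot(n_genomes >= 1L)
  structure(list(n_genomes = as.integer(n_genomes),
                 softcore_fraction = softcore_fraction,
                 softcore_min = as.integer(floor(softcore_fraction * n_genomes)),
                 cloud_max = as.integer(cloud_max)),
            class = "occupancy_policy")
}

#' Classify a pan-gene occupancy count
#'
#' @param occupancy Number of distinct genomes with a member (1..n).
#' @param policy An \code{\link{occupancy_policy}}.
#' @return One of \code{"core"}, \code{"softcore"}, \code{"shell"},
#'   \code{"cloud"}.
#' @export
classify_occupancy <- function(occupancy, policy) {
  stopifnot(inherits(policy, "occupancy_policy"))
  if (length(occupancy) != 1L || is.na(occupancy) ||
      occupancy < 1L || occupancy > policy$n_genomes)
    stop("occupancy must lie in [1, ", policy$n_genomes, "]")
  n <- policy$n_genomes
  if (occupancy == n) return("core")
  if (occupancy >= policy$softcore_min) return("softcore")
  if (occupancy <= policy$cloud_max) return("cloud")
  "shell"
}

#' Occupancy spectrum of a pan-gene matrix
#'
#' @param mat A \code{pangene_matrix}.
#' @param exclude_only_sources Optional character vector of source sets;
#'   clusters whose members all come from these sources are excluded from the
#'   spectrum (e.g. dropping clusters containing only one legacy gene model).
#' @return Named integer vector: occupancy -> cluster count.
#' @export
occupancy_spectrum <- function(mat, exclude_only_sources = NULL) {
  cl <- mat$clusters
  if (!is.null(exclude_only_sources)) {
    only <- tapply(mat$members$source_set, mat$members$cluster_id,
                   function(v) all(v %in% exclude_only_sources))
    drop_ids <- as.integer(names(only))[only]
    cl <- cl[!cl$cluster_id %in% drop_ids, , drop = FALSE]
  }
  tab <- table(factor(cl$occupancy, levels = seq_len(mat$n_genomes)))
  setNames(as.integer(tab), names(tab))
}

#' Find pan-genes segregating with a varietal family
#'
#' Selects clusters present in every genome of the target family and in at
#' most \code{max_other} genomes outside it, and reports per-family presence
#' fractions for all clusters.
#'
#' @param mat A \code{pangene_matrix}.
#' @param families Named character vector genome -> family; must cover all
#'   genomes of the matrix.
#' @param target_family Family whose private genes are sought.
#' @param max_other Maximum number of non-family genomes allowed (default 1).
#' @return list with \code{selected} (cluster ids) and \code{fractions}
#'   (data.frame cluster_id x family presence fractions).
#' @export
family_segregation <- function(mat, families, target_family, max_other = 1L) {
  if (!all(mat$genome_order %in% names(families)))
    stop("families must cover all genomes of the matrix")
  fams <- unique(unname(families[mat$genome_order]))
  if (!target_family %in% fams)
    stop("unknown family name: ", target_family)
  pres <- tapply(mat$members$genome, mat$members$cluster_id, unique)
  ids <- as.integer(names(pres))
  frac <- data.frame(cluster_id = ids)
  for (f in fams) {
    fg <- mat$genome_order[families[mat$genome_order] == f]
    frac[[f]] <- vapply(pres, function(v) length(intersect(v, fg)) / length(fg), 0)
  }
  fg <- mat$genome_order[families[mat$genome_order] == target_family]
  n_in <- vapply(pres, function(v) length(intersect(v, fg)), 0L)
  n_out <- vapply(pres, function(v) length(setdiff(v, fg)), 0L)
  selected <- ids[n_in == length(fg) & n_out <= max_other]
  list(selected = selected, fractions = frac)
}

#' Fit core-genome growth over genome-order permutations
#'
#' For each of \code{n_perm} random genome orders, the core-set size after
#' adding each genome is the number of clusters containing all genomes added
#' so far.  The decay F(g) = kappa * exp(-g / tau) + omega is then fitted by
#' nonlinear least squares.  The \code{tettelin} method fits all permutation
#' points unweighted; the \code{willenbrock} variant fits the per-g medians
#' with inverse-variance weights.  The fitted asymptote omega estimates the
#' minimal core genome.
#'
#' @param mat A \code{pangene_matrix} (>= 3 genomes).
#' @param n_perm Number of genome-order permutations (default 20).
#' @param seed RNG seed for the permutations.
#' @param method \code{"tettelin"} or \code{"willenbrock"}.
#' @return Object of class \code{growth_fit}: trajectories (n_perm x n
#'   matrix), fitted parameters kappa/tau/omega, asymptote, convergence info.
#' @export
fit_core_growth <- function(mat, n_perm = 20L, seed = 1L,
                            method = c("tettelin", "willenbrock")) {
  method <- match.arg(method)
  n <- mat$n_genomes
  if (n < 3L) stop("core-growth fitting needs at least 3 genomes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # cluster x genome presence matrix
  pres <- matrix(FALSE, nrow(mat$clusters), n,
                 dimnames = list(NULL, mat$genome_order))
  idx <- cbind(mat$members$cluster_id,
               match(mat$members$genome, mat$genome_order))
  pres[idx] <- TRUE

  traj <- matrix(NA_integer_, n_perm, n)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    acc <- rep(TRUE, nrow(pres))
    for (k in seq_len(n)) {
      acc <- acc & pres[, ord[k]]
      traj[p, k] <- sum(acc)
    }
  }

  g_all <- rep(seq_len(n), each = n_perm)
  y_all <- as.vector(traj)
  med <- apply(traj, 2L, median)
  vars <- apply(traj, 2L, stats::var)
  omega0 <- med[n]
  kappa0 <- max(mean(traj[, 1L]) - omega0, 1e-6)
  start <- list(kappa = kappa0, tau = 1, omega = omega0)

  flat <- all(abs(y_all - y_all[1L]) < .Machine$double.eps^0.5)
  if (flat) {
    params <- c(kappa = 0, tau = NA_real_, omega = unname(y_all[1L]))
    fit <- NULL
    converged <- TRUE
    note <- "constant trajectories; degenerate decay (kappa = 0)"
  } else {
    if (method == "tettelin") {
      dat <- data.frame(g = g_all, y = y_all)
      wts <- rep(1, nrow(dat))
    } else {
      w <- 1 / pmax(vars, 1e-8)
      dat <- data.frame(g = seq_len(n), y = med)
      wts <- w
    }
    fit <- try(minpack.lm::nlsLM(y ~ kappa * exp(-g / tau) + omega,
                                 data = dat, start = start, weights = wts,
                                 lower = c(0, 1e-3, 0),
                                 control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(structure(list(method = method, trajectories = traj,
                            params = NULL, asymptote = NA_real_,
                            n_perm = n_perm, seed = seed, converged = FALSE,
                            note = paste("fit failed:", as.character(fit)),
                            start = start),
                       class = "growth_fit"))
    }
    params <- coef(fit)
    converged <- TRUE
    note <- ""
  }
  structure(list(method = method, trajectories = traj,
                 params = params, asymptote = unname(params["omega"]),
                 n_perm = n_perm, seed = seed, converged = converged,
                 note = note, fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Core-genome growth fit (", x$method, "), ", x$n_perm,
      " permutations, seed ", x$seed, "\n", sep = "")
  if (!is.null(x$params)) {
    cat(sprintf("  F(g) = %.1f * exp(-g / %.3f) + %.1f\n",
                x$params["kappa"], x$params["tau"], x$params["omega"]))
    cat(sprintf("  asymptote (core-genome size): %.1f\n", x$asymptote))
  } else {
    cat("  fit did not converge:", x$note, "\n")
  }
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$params

#' @export
summary.growth_fit <- function(object, ...) {
  n <- ncol(object$trajectories)
  data.frame(g = seq_len(n),
             mean = colMeans(object$trajectories),
             median = apply(object$trajectories, 2L, median),
             sd = apply(object$trajectories, 2L, sd),
             fitted = if (!is.null(object$params))
               predict(object, seq_len(n)) else NA_real_)
}

#' Predict core-set size at a genome count
#' @param object A \code{growth_fit}.
#' @param newdata Genome counts (numeric vector); default observed range.
#' @param ... Unused.
#' @return Predicted core-set sizes.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$params)) stop("fit did not converge")
  if (is.null(newdata)) newdata <- seq_len(ncol(object$trajectories))
  p <- object$params
  if (is.na(p["tau"])) return(rep(unname(p["omega"]), length(newdata)))
  unname(p["kappa"] * exp(-newdata / p["tau"]) + p["omega"])
}

#' Plot permutation trajectories and the fitted decay
#' @param x A \code{growth_fit}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.growth_fit <- function(x, ...) {
  n <- ncol(x$trajectories)
  graphics::matplot(seq_len(n), t(x$trajectories), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.4),
                    xlab = "genomes added", ylab = "core-set size", ...)
  if (!is.null(x$params)) {
    gg <- seq(1, n, length.out = 100)
    graphics::lines(gg, predict(x, gg), col = "red", lwd = 2)
  }
  invisible(x)
}
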