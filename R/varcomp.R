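#' Additive + dominance variance components by REML
#'
#' Fits y = mu + u_A + u_D + e with u_A ~ N(0, A sigma2_A),
#' u_D ~ N(0, D sigma2_D) by restricted maximum likelihood:
#' expectation-maximization updates (monotone in the restricted
#' log-likelihood) accelerated by average-information steps that are only
#' accepted when they do not decrease the likelihood; non-negativity is
#' enforced by projecting components onto a small positive floor. Narrow-
#' sense heritability is reported as sigma2_A over the total phenotypic
#' variance (sigma2_A + sigma2_D + sigma2_e).
#'
#' @param y response vector.
#' @param A additive relationship matrix (`fs_relmat` or plain matrix, PSD).
#' @param D optional dominance relationship matrix; an all-zero or `NULL` D
#'   drops the dominance component.
#' @param max_iter,tol iteration cap and log-likelihood convergence
#'   tolerance.
#' @return `fs_varcomp`: sigma2_A, sigma2_D, sigma2_e, h2, convergence info
#'   and the log-likelihood trace.
#' @export
fit_ad_mixed_model <- function(y, A, D = NULL, max_iter = 200, tol = 1e-8) {
  get_vals <- function(m) if (inherits(m, "fs_relmat")) m$values else as.matrix(m)
  A <- get_vals(A)
  n <- length(y)
  stopifnot(nrow(A) == n)
  check_psd <- function(m, name) {
    ev <- min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-6 * max(1, max(abs(m))))
      stop(name, " is not positive semi-definite (min eigenvalue ", ev, ")")
  }
  check_psd(A, "A")
  Gs <- list(A = A)
  if (!is.null(D)) {
    D <- get_vals(D)
    if (any(D != 0)) { check_psd(D, "D"); Gs$D <- D }
  }
  Gs$E <- diag(n)
  k <- length(Gs)
  vy <- var(y)
  if (vy == 0) stop("zero-variance response")
  sigma2 <- rep(vy / k, k)
  names(sigma2) <- names(Gs)
  floor_val <- 1e-8 * vy
  X <- matrix(1, n, 1)

  reml_pieces <- function(sigma2) {
    V <- matrix(0, n, n)
    for (j in seq_len(k)) V <- V + sigma2[j] * Gs[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    P <- Vinv - VinvX %*% solve(XtVinvX, t(VinvX))
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtVinvX)$modulus[1] +
                    sum(y * Py))
    list(P = P, Py = Py, ll = as.numeric(ll))
  }

  pieces <- reml_pieces(sigma2)
  if (is.null(pieces)) stop("initial variance matrix not invertible")
  trace <- pieces$ll
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    P <- pieces$P; Py <- pieces$Py
    GPy <- lapply(Gs, function(G) G %*% Py)
    quad <- vapply(GPy, function(g) sum(Py * g), 0)       # y'P G P y
    trPG <- vapply(Gs, function(G) sum(P * G), 0)          # tr(P G), symmetric G

    em_step <- sigma2 + sigma2^2 * (quad - trPG) / n
    em_step <- pmax(em_step, floor_val)

    proposal <- em_step
    if (it > 3) {
      # average-information step, accepted only if it improves the likelihood
      AI <- matrix(0, k, k)
      for (a in seq_len(k)) for (b in a:k) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum(GPy[[a]] * (P %*% GPy[[b]]))
      }
      score <- -0.5 * (trPG - quad)
      ai_step <- tryCatch(sigma2 + solve(AI, score), error = function(e) NULL)
      if (!is.null(ai_step) && all(is.finite(ai_step)))
        proposal <- pmax(ai_step, floor_val)
    }

    cand <- reml_pieces(proposal)
    if (is.null(cand) || cand$ll < pieces$ll - 1e-10) {
      proposal <- em_step
      cand <- reml_pieces(proposal)
      if (is.null(cand)) break
    }
    delta_ll <- cand$ll - pieces$ll
    sigma2 <- proposal
    pieces <- cand
    trace <- c(trace, pieces$ll)
    if (abs(delta_ll) < tol) { converged <- TRUE; break }
  }

  out <- c(A = unname(sigma2["A"]),
           D = unname(if ("D" %in% names(sigma2)) sigma2["D"] else 0),
           E = unname(sigma2["E"]))
  out[out <= 2 * floor_val] <- 0
  h2 <- out["A"] / sum(out)
  structure(list(sigma2_A = unname(out["A"]), sigma2_D = unname(out["D"]),
                 sigma2_e = unname(out["E"]), h2 = unname(h2),
                 converged = converged, iterations = length(trace) - 1,
                 loglik_trace = trace),
            class = "fs_varcomp")
}

#' @export
print.fs_varcomp <- function(x, ...) {
  cat(sprintf(paste0("<fs_varcomp> sigma2_A = %.4g, sigma2_D = %.4g, ",
                     "sigma2_e = %.4g, h2 = %.3f (%s, %d iterations)\n"),
              x$sigma2_A, x$sigma2_D, x$sigma2_e, x$h2,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Heritability for every environment of a fitness table
#' @param fitness an `fs_fitness`.
#' @param A,D relationship matrices.
#' @param ... passed to [fit_ad_mixed_model()].
#' @return data.frame with one row per environment.
#' @export
heritability_by_environment <- function(fitness, A, D = NULL, ...) {
  rows <- lapply(fitness$environments, function(e) {
    vc <- fit_ad_mixed_model(fitness$values[, e], A, D, ...)
    data.frame(environment = e, sigma2_A = vc$sigma2_A, sigma2_D = vc$sigma2_D,
               sigma2_e = vc$sigma2_e, h2 = vc$h2, converged = vc$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
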