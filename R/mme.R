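## Weighted linear mixed models for deregressed proofs: y = 1 mu + Z a + e,
## a ~ N(0, G sigma2_a) per genetic component, e ~ N(0, D sigma2_e) with
## d_jj = (1 - r2_j)/r2_j. Variance components by restricted maximum
## likelihood (average-information iterations, damped EM fallback); breeding
## values by the BLUP identities mu = GLS mean, a_k = sigma2_k G_k Z' V^-1
## (y - 1 mu), which also predicts animals without records through their
## relationships.

## records used in a fit: usable DRP, animal present in the matrices,
## optionally restricted to a reference set
.fitRecords <- function(drp, ids, recordIds = NULL) {
  recs <- drpRecords(drp)
  recs <- recs[recs$usable & recs$animal_id %in% as.integer(ids), ]
  if (!is.null(recordIds))
    recs <- recs[recs$animal_id %in% as.integer(recordIds), ]
  recs
}

.checkAligned <- function(relmats) {
  ids <- animalIds(relmats[[1]])
  for (m in relmats[-1])
    if (!identical(animalIds(m), ids))
      stop("relationship matrices carry mismatched animal id sets")
  ids
}

#' Solve the weighted mixed-model equations at fixed variance components
#'
#' @param drp a [DRPRecords-class]; only usable records of animals present in
#'   the relationship matrices contribute.
#' @param relmats one [RelationshipMatrix-class] or a list of one or two
#'   (the genetic components); all must be over the same animals. Every
#'   animal in the matrices receives an EBV, with or without a record.
#' @param varcomp a [VarianceComponents-class] with one additive variance per
#'   relationship matrix.
#' @param recordIds optional restriction of the records used (e.g. the
#'   reference population), leaving the remaining animals prediction-only.
#' @return an [EBVSet-class] with per-component contributions.
#' @export
solveMME <- function(drp, relmats, varcomp, recordIds = NULL) {
  if (is(relmats, "RelationshipMatrix")) relmats <- list(relmats)
  ids <- .checkAligned(relmats)
  s2 <- sigma2Additive(varcomp)
  if (length(s2) != length(relmats))
    stop("need one additive variance per relationship matrix")
  if (sigma2Residual(varcomp) <= 0) stop("residual variance must be > 0")
  recs <- .fitRecords(drp, ids, recordIds)
  if (nrow(recs) < 1) stop("no usable records among the matrix animals")
  ri <- match(as.character(recs$animal_id), ids)
  y <- recs$drp
  d <- recs$weight_d

  V <- diag(sigma2Residual(varcomp) * d)
  for (k in seq_along(relmats))
    V <- V + s2[k] * relMatrix(relmats[[k]])[ri, ri]
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular phenotypic covariance; stabilize G (PSD jitter) or check ",
         "variance components", call. = FALSE))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, length(y))))
  mu <- sum(Vi_y) / sum(Vi_1)
  Vi_r <- Vi_y - mu * Vi_1

  comp <- matrix(0, length(ids), length(relmats))
  tags <- vapply(relmats, componentTag, character(1))
  if (anyDuplicated(tags)) tags <- make.unique(tags)
  colnames(comp) <- tags
  for (k in seq_along(relmats))
    comp[, k] <- s2[k] * (relMatrix(relmats[[k]])[, ri, drop = FALSE] %*%
                            Vi_r)
  EBVSet(ids, mu, comp)
}

## ---------------------------------------------------------------------------
## REML
## ---------------------------------------------------------------------------

## One-component fast path: eigendecompose C = D^-1/2 K D^-1/2 once; every
## iteration is then O(n). Exact, same restricted likelihood as the dense
## path.
.remlEigen <- function(y, d, K, init, tol, maxIter, floor = 1e-8) {
  ds <- sqrt(d)
  C <- K / tcrossprod(ds)
  ee <- eigen(C, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  z <- crossprod(ee$vectors, y / ds)[, 1]
  w <- crossprod(ee$vectors, 1 / ds)[, 1]
  n <- length(y)
  logDetD <- sum(log(d))
  theta <- init
  traj <- list()
  llPrev <- -Inf
  for (it in seq_len(maxIter)) {
    v <- theta[1] * lam + theta[2]
    muHat <- sum(w * z / v) / sum(w^2 / v)
    t_ <- (z - muHat * w) / v
    ll <- -0.5 * (logDetD + sum(log(v)) + log(sum(w^2 / v)) +
                    sum((z - muHat * w)^2 / v))
    yPKPy <- sum(lam * t_^2)
    yPDPy <- sum(t_^2)
    trPK <- sum(lam / v) - sum(w^2 * lam / v^2) / sum(w^2 / v)
    trPD <- sum(1 / v) - sum(w^2 / v^2) / sum(w^2 / v)
    score <- -0.5 * c(trPK - yPKPy, trPD - yPDPy)
    quadKK <- sum(lam^2 * t_^2 / v) -
      sum(lam * t_ * w / v)^2 / sum(w^2 / v)
    quadKD <- sum(lam * t_^2 / v) -
      sum(lam * t_ * w / v) * sum(t_ * w / v) / sum(w^2 / v)
    quadDD <- sum(t_^2 / v) - sum(t_ * w / v)^2 / sum(w^2 / v)
    AI <- 0.5 * matrix(c(quadKK, quadKD, quadKD, quadDD), 2, 2)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    newTheta <- if (!is.null(step)) {
      # damp AI steps that would leave the parameter space: at most a
      # ten-fold decrease per iteration keeps every component positive
      pmax(theta + step, theta / 10)
    } else {
      # EM-style update (Johnson & Thompson) when the AI system is singular
      pmax(theta + theta^2 / n * c(yPKPy - trPK, yPDPy - trPD), floor)
    }
    traj[[it]] <- newTheta
    delta <- max(abs(newTheta - theta) / pmax(abs(theta), 1e-6))
    plateau <- it > 1 && abs(ll - llPrev) < 1e-9 * (1 + abs(ll))
    llPrev <- ll
    theta <- pmax(newTheta, floor)
    if (delta < tol || plateau) {
      v <- theta[1] * lam + theta[2]
      muHat <- sum(w * z / v) / sum(w^2 / v)
      ll <- -0.5 * (logDetD + sum(log(v)) + log(sum(w^2 / v)) +
                      sum((z - muHat * w)^2 / v))
      return(list(theta = theta, loglik = ll, niter = it, converged = TRUE,
                  traj = traj))
    }
  }
  list(theta = theta, loglik = NA_real_, niter = maxIter, converged = FALSE,
       traj = traj)
}

## General dense path for >= 2 genetic components.
.remlDense <- function(y, d, Klist, init, tol, maxIter, floor = 1e-8) {
  n <- length(y)
  nk <- length(Klist)
  Vparts <- c(Klist, list(diag(d)))
  theta <- init
  traj <- list()
  llPrev <- -Inf
  for (it in seq_len(maxIter)) {
    V <- matrix(0, n, n)
    for (k in seq_along(Vparts)) V <- V + theta[k] * Vparts[[k]]
    ch <- tryCatch(chol(V), error = function(e)
      stop("REML: singular V at iteration ", it, call. = FALSE))
    Vi <- chol2inv(ch)
    Vi1 <- Vi %*% rep(1, n)
    P <- Vi - tcrossprod(Vi1) / sum(Vi1)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + log(sum(Vi1)) +
                    crossprod(y, Py)[1])
    score <- numeric(nk + 1)
    quad <- numeric(nk + 1)
    VkPy <- vector("list", nk + 1)
    for (k in seq_along(Vparts)) {
      VkPy[[k]] <- Vparts[[k]] %*% Py
      quad[k] <- crossprod(Py, VkPy[[k]])[1]
      score[k] <- -0.5 * (sum(P * Vparts[[k]]) - quad[k])
    }
    AI <- matrix(0, nk + 1, nk + 1)
    for (k in seq_len(nk + 1)) for (l in k:(nk + 1)) {
      AI[k, l] <- AI[l, k] <- 0.5 * crossprod(VkPy[[k]], P %*% VkPy[[l]])[1]
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    newTheta <- if (!is.null(step)) {
      pmax(theta + step, theta / 10)   # damped AI, see the eigen path
    } else {
      trPV <- quad - 2 * score
      pmax(theta + theta^2 / n * (quad - trPV), floor)
    }
    traj[[it]] <- newTheta
    delta <- max(abs(newTheta - theta) / pmax(abs(theta), 1e-6))
    plateau <- it > 1 && abs(ll - llPrev) < 1e-9 * (1 + abs(ll))
    llPrev <- ll
    theta <- pmax(newTheta, floor)
    if (delta < tol || plateau) {
      V <- matrix(0, n, n)
      for (k in seq_along(Vparts)) V <- V + theta[k] * Vparts[[k]]
      ch <- chol(V)
      Vi1 <- chol2inv(ch) %*% rep(1, n)
      Viy <- chol2inv(ch) %*% y
      muHat <- sum(Viy) / sum(Vi1)
      ll <- -0.5 * (2 * sum(log(diag(ch))) + log(sum(Vi1)) +
                      crossprod(y - muHat, Viy - muHat * Vi1)[1])
      return(list(theta = theta, loglik = ll, niter = it, converged = TRUE,
                  traj = traj))
    }
  }
  list(theta = theta, loglik = NA_real_, niter = maxIter, converged = FALSE,
       traj = traj)
}

#' Restricted maximum likelihood for the weighted model
#'
#' Average-information REML with damped EM-style fallback steps whenever an
#' AI update would leave the parameter space; estimates are floored at a
#' small positive value. One-component fits use an exact eigendecomposition
#' fast path.
#'
#' @param drp a [DRPRecords-class].
#' @param relmats one or a list of [RelationshipMatrix-class] objects.
#' @param init optional [VarianceComponents-class] starting values; default
#'   splits half the phenotypic variance equally across components.
#' @param tol relative-change convergence tolerance.
#' @param maxIter iteration cap; non-convergence is an error reporting the
#'   trajectory tail.
#' @param recordIds optional restriction of the records used.
#' @return a [VarianceComponents-class].
#' @export
remlEstimate <- function(drp, relmats, init = NULL, tol = 1e-6,
                         maxIter = 100, recordIds = NULL) {
  if (is(relmats, "RelationshipMatrix")) relmats <- list(relmats)
  ids <- .checkAligned(relmats)
  recs <- .fitRecords(drp, ids, recordIds)
  if (nrow(recs) < 2) stop("REML needs at least 2 records")
  ri <- match(as.character(recs$animal_id), ids)
  y <- recs$drp
  d <- recs$weight_d
  nk <- length(relmats)
  vp <- var(y)
  theta0 <- if (is.null(init)) c(rep(0.5 * vp / nk, nk), 0.5 * vp)
            else c(sigma2Additive(init), sigma2Residual(init))
  Klist <- lapply(relmats, function(m)
    .stabilize(relMatrix(m)[ri, ri, drop = FALSE]))
  fit <- if (nk == 1)
    .remlEigen(y, d, Klist[[1]], theta0, tol, maxIter)
  else .remlDense(y, d, Klist, theta0, tol, maxIter)
  if (!fit$converged) {
    tail_ <- utils::tail(fit$traj, 3)
    stop("REML did not converge in ", maxIter, " iterations; last updates: ",
         paste(vapply(tail_, function(t) paste(signif(t, 4), collapse = "/"),
                      character(1)), collapse = " -> "))
  }
  s2 <- fit$theta[seq_len(nk)]
  names(s2) <- vapply(relmats, componentTag, character(1))
  if (anyDuplicated(names(s2))) names(s2) <- make.unique(names(s2))
  VarianceComponents(s2, fit$theta[nk + 1], loglik = fit$loglik,
                     niter = fit$niter, converged = TRUE)
}

#' Fit a PBLUP or GBLUP model end to end
#'
#' Builds the relationship matrices, estimates variance components by REML
#' (unless supplied), and solves for breeding values. `"PBLUP"` uses the
#' pedigree numerator matrix traced three generations back; `"G1"` one
#' genomic matrix over `snpSubset`; `"G2"` separate chip (`"CHIP"`) and
#' selected-WGS (`"WGS"` union) components with zero covariance between them.
#'
#' @param modelName `"PBLUP"`, `"G1"` or `"G2"`.
#' @param drp a [DRPRecords-class].
#' @param data a [PedigreeTable-class] (PBLUP) or [GenotypePanel-class]
#'   (G1/G2).
#' @param snpSubset SNP subset for G1 (default `"ALL"`).
#' @param referenceIds records used for estimation; remaining animals are
#'   prediction-only. Default: all usable records.
#' @param animals animals to carry in the matrices (default: all animals in
#'   `drp` present in `data`).
#' @param varcomp optional fixed [VarianceComponents-class] (skips REML).
#' @param tol,maxIter REML controls.
#' @return list with elements `varcomp` and `ebv`.
#' @export
fitModel <- function(modelName = c("G1", "G2", "PBLUP"), drp, data,
                     snpSubset = "ALL", referenceIds = NULL, animals = NULL,
                     varcomp = NULL, tol = 1e-6, maxIter = 100) {
  modelName <- match.arg(modelName)
  recs <- drpRecords(drp)
  if (is.null(animals)) {
    pool <- if (is(data, "PedigreeTable")) animalIds(data)
            else as.integer(animalIds(data))
    animals <- intersect(recs$animal_id, pool)
  }
  relmats <- switch(modelName,
    PBLUP = {
      if (!is(data, "PedigreeTable")) stop("PBLUP needs a PedigreeTable")
      list(computeA(data, animals))
    },
    G1 = {
      if (!is(data, "GenotypePanel")) stop("G1 needs a GenotypePanel")
      g <- computeGVanRaden(data[, as.character(animals)], snpSubset)
      list(g)
    },
    G2 = {
      if (!is(data, "GenotypePanel")) stop("G2 needs a GenotypePanel")
      if (!length(panelSnpIds(data, "WGS")))
        stop("G2 requested but the selected-WGS panel is empty")
      sub <- data[, as.character(animals)]
      list(computeGVanRaden(sub, "CHIP"), computeGVanRaden(sub, "WGS"))
    })
  if (is.null(varcomp))
    varcomp <- remlEstimate(drp, relmats, tol = tol, maxIter = maxIter,
                            recordIds = referenceIds)
  ebv <- solveMME(drp, relmats, varcomp, recordIds = referenceIds)
  list(varcomp = varcomp, ebv = ebv)
}
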