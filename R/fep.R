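## Alchemical binding-free-energy aggregation: per-lambda-window free
## energies via the Bennett acceptance ratio (general unequal-sample-count
## form), window chaining over each annihilation leg, the double-annihilation
## binding cycle with Coulomb/van der Waals decomposition, replica-spread
## uncertainties, and mutant comparison. Energies in kcal/mol; k_B*T handled
## internally.

#' Construct a WorkSamples object for one lambda window
#'
#' @param lambdaFrom,lambdaTo window endpoints in [0,1].
#' @param forward work values (kcal/mol) for the from->to perturbation.
#' @param reverse work values (kcal/mol) for the to->from perturbation.
#' @param temperature K (default 300).
#' @return a \linkS4class{WorkSamples}
#' @export
workSamples <- function(lambdaFrom, lambdaTo, forward, reverse,
                        temperature = 300) {
  new("WorkSamples", lambdaFrom = lambdaFrom, lambdaTo = lambdaTo,
      forward = as.numeric(forward), reverse = as.numeric(reverse),
      temperature = temperature)
}

setMethod("show", "WorkSamples", function(object) {
  cat(sprintf(
    "WorkSamples [%.3f -> %.3f] at %g K: %d forward, %d reverse\n",
    object@lambdaFrom, object@lambdaTo, object@temperature,
    length(object@forward), length(object@reverse)))
})

#' Bennett acceptance ratio estimate for one window
#'
#' Solves the Bennett self-consistency equation
#' \deqn{\sum_F [1+e^{M+\beta(W_F - \Delta G)}]^{-1} =
#'       \sum_R [1+e^{-(M+\beta(-W_R - \Delta G))}]^{-1}}
#' (with \eqn{M = \log(n_F/n_R)}, so unequal sample counts are handled) by
#' damped Newton iteration with a bisection fallback; the left-minus-right
#' residual is monotone in \eqn{\Delta G}, so the bracketed solve always
#' converges. The standard error is the Bennett asymptotic estimate
#' \deqn{\beta^2 se^2 = [\sum_i (2+2\cosh x_i)^{-1}]^{-1} - (1/n_F + 1/n_R)}
#' over the combined samples. Windows whose work distributions barely overlap
#' are flagged \code{lowOverlap} (attribute on the return), never silent.
#'
#' @param samples a \linkS4class{WorkSamples}.
#' @param tolerance convergence tolerance on dG, kcal/mol (default 1e-10).
#' @param maxIter maximum Newton iterations (default 200).
#' @return named numeric c(dG, se) with attribute \code{lowOverlap}
#' @export
barWindow <- function(samples, tolerance = 1e-10, maxIter = 200L) {
  wf <- samples@forward
  wr <- samples@reverse
  if (length(wf) < 2L || length(wr) < 2L)
    .stopf("BAR needs at least 2 samples in each direction")
  beta <- 1 / (.kB * samples@temperature)
  M <- log(length(wf) / length(wr))
  ## energy-difference samples: forward works and negated reverse works
  uR <- -wr
  resid <- function(dG) {
    hF <- M + beta * (wf - dG)
    hR <- M + beta * (uR - dG)
    sum(stats::plogis(-hF)) - sum(stats::plogis(hR))
  }
  ## resid is increasing in dG; bracket the root
  lo <- min(wf, uR) - 10 / beta
  hi <- max(wf, uR) + 10 / beta
  while (resid(lo) > 0) lo <- lo - 50 / beta
  while (resid(hi) < 0) hi <- hi + 50 / beta
  dG <- (mean(wf) + mean(uR)) / 2
  dG <- min(max(dG, lo), hi)
  for (it in seq_len(maxIter)) {
    f <- resid(dG)
    if (f < 0) lo <- max(lo, dG) else hi <- min(hi, dG)
    ## derivative of resid wrt dG (both sums increase)
    hF <- M + beta * (wf - dG)
    hR <- M + beta * (uR - dG)
    df <- beta * (sum(stats::plogis(-hF) * stats::plogis(hF)) +
                  sum(stats::plogis(hR) * stats::plogis(-hR)))
    step <- if (df > 0) -f / df else NA_real_
    cand <- dG + ifelse(is.finite(step), step, 0)
    if (!is.finite(cand) || cand <= lo || cand >= hi)
      cand <- (lo + hi) / 2                  # bisection fallback
    if (abs(cand - dG) < tolerance) { dG <- cand; break }
    dG <- cand
  }
  ## Bennett asymptotic variance over combined samples
  x <- c(M + beta * (wf - dG), M + beta * (uR - dG))
  s <- sum(1 / (2 + 2 * cosh(x)))
  v <- 1 / s - (1 / length(wf) + 1 / length(wr))
  lowOverlap <- !is.finite(v) || v <= 0 || s < 1e-8
  se <- if (v > 0) sqrt(v) / beta else Inf
  out <- c(dG = dG, se = se)
  attr(out, "lowOverlap") <- lowOverlap
  out
}

#' Free energy of one annihilation leg by chaining lambda windows
#'
#' The windows must tile [0,1] contiguously (lambda_to of each window equals
#' lambda_from of the next). Window estimates are summed; standard errors are
#' combined as sqrt of the summed variances (windows treated independent).
#'
#' @param windows list of \linkS4class{WorkSamples} (any order).
#' @param name "coulomb" or "vdw".
#' @param environment "complex" or "solvent".
#' @param replica integer replica index (default 1).
#' @return a \linkS4class{LegResult}
#' @export
legFreeEnergy <- function(windows, name, environment, replica = 1L) {
  if (!length(windows)) .stopf("no windows supplied")
  froms <- vapply(windows, function(w) w@lambdaFrom, 1.0)
  windows <- windows[order(froms)]
  froms <- sort(froms)
  tos <- vapply(windows, function(w) w@lambdaTo, 1.0)
  tol <- 1e-9
  breaksBad <- c(
    if (abs(froms[1]) > tol) froms[1],
    if (abs(tos[length(tos)] - 1) > tol) tos[length(tos)],
    tos[-length(tos)][abs(tos[-length(tos)] - froms[-1]) > tol])
  if (length(breaksBad))
    .stopf("lambda windows do not tile [0,1]; break at: %s",
           paste(format(breaksBad), collapse = ", "))
  est <- lapply(windows, barWindow)
  dGs <- vapply(est, `[[`, 1.0, "dG")
  ses <- vapply(est, `[[`, 1.0, "se")
  low <- vapply(est, function(e) attr(e, "lowOverlap"), TRUE)
  new("LegResult", name = name, environment = environment,
      replica = as.integer(replica), windowDGs = dGs, dG = sum(dGs),
      se = sqrt(sum(ses^2)), lowOverlap = low)
}

setMethod("show", "LegResult", function(object) {
  cat(sprintf(
    "LegResult %s/%s replica %d: dG %.3f +/- %.3f kcal/mol (%d windows%s)\n",
    object@name, object@environment, object@replica, object@dG, object@se,
    length(object@windowDGs),
    if (any(object@lowOverlap)) ", LOW OVERLAP" else ""))
})

#' Double-annihilation binding free energy with component decomposition
#'
#' Per replica and component, \code{dG_bind = dG_annihilate(solvent) -
#' dG_annihilate(complex)} (binding-favourable values negative). When the two
#' environments carry the same replica indices the cycle is closed replica by
#' replica; with unequal replica protocols (e.g. five complex production runs
#' against three solvated-ligand runs) each complex replica is combined with
#' the replica mean of the solvent legs. The reported value is the mean over
#' complex replicas; \code{replicaSd} is the SD across those replica means of
#' the total (the spread across independent production runs); the BAR
#' asymptotic se propagated through the cycle is reported separately.
#'
#' @param complexLegs,solventLegs lists of \linkS4class{LegResult}s covering a
#'   coulomb and a vdw leg for every replica in each environment.
#' @param label character label (e.g. the mutant name).
#' @return a \linkS4class{BindingFreeEnergy}
#' @export
bindingFreeEnergy <- function(complexLegs, solventLegs, label = "") {
  envOf <- function(ls) vapply(ls, function(l) l@environment, "")
  if (!all(envOf(complexLegs) == "complex") ||
      !all(envOf(solventLegs) == "solvent"))
    .stopf("legs supplied under the wrong environment")
  repC <- sort(unique(vapply(complexLegs, function(l) l@replica, 1L)))
  repS <- sort(unique(vapply(solventLegs, function(l) l@replica, 1L)))
  paired <- identical(repC, repS)
  find <- function(ls, nm, rep) {
    hit <- Filter(function(l) l@name == nm && l@replica == rep, ls)
    if (length(hit) != 1L)
      .stopf("incomplete cycle: need exactly one %s leg for replica %d",
             nm, rep)
    hit[[1]]
  }
  ## solvent contribution per component: replica-matched leg or replica mean
  solventDG <- function(nm, rep) {
    if (paired) {
      l <- find(solventLegs, nm, rep)
      c(dG = l@dG, var = l@se^2)
    } else {
      ls <- Filter(function(l) l@name == nm, solventLegs)
      if (!length(ls))
        .stopf("incomplete cycle: no %s leg in the solvent environment", nm)
      c(dG = mean(vapply(ls, function(l) l@dG, 1.0)),
        var = sum(vapply(ls, function(l) l@se^2, 1.0)) / length(ls)^2)
    }
  }
  per <- data.frame(replica = repC, coulomb = NA_real_, vdw = NA_real_,
                    total = NA_real_)
  varAsym <- 0
  for (i in seq_along(repC)) {
    r <- repC[i]
    for (nm in c("coulomb", "vdw")) {
      sv <- solventDG(nm, r)
      cx <- find(complexLegs, nm, r)
      per[[nm]][i] <- sv[["dG"]] - cx@dG
      varAsym <- varAsym + sv[["var"]] + cx@se^2
    }
    per$total[i] <- per$coulomb[i] + per$vdw[i]
  }
  new("BindingFreeEnergy",
      dGTotal = mean(per$total), dGCoulomb = mean(per$coulomb),
      dGVdw = mean(per$vdw),
      replicaSd = if (length(repC) > 1L) sd(per$total) else NA_real_,
      nReplicas = length(repC), perReplica = per,
      asymptoticSe = sqrt(varAsym) / length(repC), label = label)
}

setMethod("show", "BindingFreeEnergy", function(object) {
  cat(sprintf(
    "BindingFreeEnergy%s: %.2f kcal/mol (coulomb %.2f, vdw %.2f), replica sd %.2f (n=%d)\n",
    if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
    object@dGTotal, object@dGCoulomb, object@dGVdw, object@replicaSd,
    object@nReplicas))
})

#' Compare binding free energies across mutants
#'
#' Ranks a labelled set of \linkS4class{BindingFreeEnergy} results, reports
#' the pairwise ddG against a reference label, attributes each ddG to the
#' component (coulomb or vdw) carrying at least half of its magnitude, and
#' tests replica means with an unpaired two-sample t-test. With a single
#' replica no test is run and the row is flagged.
#'
#' @param results named list of \linkS4class{BindingFreeEnergy}s (>= 2).
#' @param reference label to compare against (default: first).
#' @return data.frame(label, dG, replica_sd, ddG_vs_ref, ddG_coulomb, ddG_vdw,
#'   attribution, p_value, flagged), ranked by dG (strongest binder first)
#' @export
compareMutants <- function(results, reference = names(results)[1]) {
  if (length(results) < 2L) .stopf("need at least 2 labelled results")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    .stopf("results must be a named list")
  if (!reference %in% names(results))
    .stopf("unknown reference label '%s'", reference)
  ref <- results[[reference]]
  rows <- lapply(names(results), function(lb) {
    x <- results[[lb]]
    ddG <- x@dGTotal - ref@dGTotal
    dc <- x@dGCoulomb - ref@dGCoulomb
    dv <- x@dGVdw - ref@dGVdw
    attribution <- if (lb == reference) ""
      else if (abs(dv) >= 0.5 * abs(ddG)) "vdw" else "coulomb"
    single <- x@nReplicas < 2L || ref@nReplicas < 2L
    p <- if (lb == reference) NA_real_ else if (single) NA_real_
      else stats::t.test(x@perReplica$total, ref@perReplica$total,
                         var.equal = FALSE)$p.value
    data.frame(label = lb, dG = x@dGTotal, replica_sd = x@replicaSd,
               ddG_vs_ref = ddG, ddG_coulomb = dc, ddG_vdw = dv,
               attribution = attribution, p_value = p,
               flagged = single && lb != reference,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dG), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  out
}

## ---- work-table I/O ---------------------------------------------------

#' Read a delimited work-sample table
#'
#' Expected columns: lambda_from, lambda_to, direction ("forward"/"reverse"),
#' work_kcal_mol, replica, component ("coulomb"/"vdw"), environment
#' ("complex"/"solvent"). Whitespace- or tab-delimited with a header;
#' '#' comment lines ignored.
#'
#' @param path file path (or a data.frame already in this layout).
#' @return data.frame
#' @export
readWorkTable <- function(path) {
  df <- if (is.data.frame(path)) path
    else utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("lambda_from", "lambda_to", "direction", "work_kcal_mol",
            "replica", "component", "environment")
  if (!all(need %in% names(df)))
    .stopf("work table must have columns: %s", paste(need, collapse = ", "))
  df
}

#' Full free-energy aggregation from a work table
#'
#' Groups the table by environment, component and replica, chains each leg's
#' windows through \code{\link{barWindow}} and closes the double-annihilation
#' cycle with \code{\link{bindingFreeEnergy}}.
#'
#' @param table data.frame or path accepted by \code{\link{readWorkTable}}.
#' @param temperature K (default 300).
#' @param label label for the result.
#' @return a \linkS4class{BindingFreeEnergy}
#' @export
fepAnalysis <- function(table, temperature = 300, label = "") {
  df <- readWorkTable(table)
  legsOf <- function(envName) {
    sub <- df[df$environment == envName, , drop = FALSE]
    if (!nrow(sub)) .stopf("incomplete cycle: no %s legs in table", envName)
    out <- list()
    for (nm in unique(sub$component)) for (r in sort(unique(sub$replica))) {
      s2 <- sub[sub$component == nm & sub$replica == r, , drop = FALSE]
      if (!nrow(s2)) next
      wins <- lapply(split(s2, paste(s2$lambda_from, s2$lambda_to)), function(w) {
        workSamples(w$lambda_from[1], w$lambda_to[1],
                    w$work_kcal_mol[w$direction == "forward"],
                    w$work_kcal_mol[w$direction == "reverse"], temperature)
      })
      out[[length(out) + 1L]] <- legFreeEnergy(wins, nm, envName, r)
    }
    out
  }
  bindingFreeEnergy(legsOf("complex"), legsOf("solvent"), label = label)
}
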