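#' The lactate + acetate to butyrate reaction network
#'
#' Stoichiometric model of the proposed pathway: electron-bifurcating lactate
#' oxidation (LDH/EtfAB), ferredoxin-reducing pyruvate oxidation (pyruvate:
#' ferredoxin oxidoreductase, the clostridial norm), thiolase condensation of
#' two acetyl-CoA, reduction through 3-hydroxybutyryl-CoA and crotonase to
#' crotonyl-CoA, electron-bifurcating crotonyl-CoA reduction (Bcd/EtfAB),
#' butyrate release via phosphotransbutyrylase/butyrate kinase or via
#' butyryl-CoA:acetate CoA-transferase (which activates external acetate),
#' acetate kinase in both directions (release, and ATP-dependent uptake),
#' the acetaldehyde/alcohol dehydrogenase ethanol route, a ferredoxin
#' hydrogenase, a ferredoxin:NAD+ oxidoreductase, a chemiosmotically coupled
#' ATP synthase/hydrolysis pair (ion-gradient bookkeeping is not modelled),
#' and a biomass sink drawing acetyl-CoA with an adjustable electron content
#' (the `biomass_e` exchange pair).
#'
#' All reactions balance carbon exactly and balance electrons under
#' degree-of-reduction bookkeeping (NADH and reduced ferredoxin carry 2
#' electrons each); see [check_reaction()].
#'
#' @param registry metabolite registry.
#' @return an object of class `reaction_network`: list with the
#'   stoichiometric matrix `S` (species x reactions), `species` tibble
#'   (name, nC, gamma, role) and `reactions` tibble (name, equation).
#' @export
reaction_network <- function(registry = metabolite_registry()) {
  rxn <- list(
    LDH_EtfAB = c("lactate" = -1, "NAD" = -2, "Fd_red" = -1,
                  "pyruvate" = 1, "NADH" = 2, "Fd_ox" = 1),
    PFOR = c("pyruvate" = -1, "CoA" = -1, "Fd_ox" = -1,
             "acetyl-CoA" = 1, "CO2" = 1, "Fd_red" = 1),
    thiolase = c("acetyl-CoA" = -2, "acetoacetyl-CoA" = 1, "CoA" = 1),
    HBD = c("acetoacetyl-CoA" = -1, "NADH" = -1,
            "3-hydroxybutyryl-CoA" = 1, "NAD" = 1),
    crotonase = c("3-hydroxybutyryl-CoA" = -1, "crotonyl-CoA" = 1,
                  "H2O" = 1),
    BCD_EtfAB = c("crotonyl-CoA" = -1, "NADH" = -2, "Fd_ox" = -1,
                  "butyryl-CoA" = 1, "NAD" = 2, "Fd_red" = 1),
    PTB_BUK = c("butyryl-CoA" = -1, "ADP" = -1, "Pi" = -1,
                "butyrate" = 1, "CoA" = 1, "ATP" = 1),
    CoA_transferase = c("butyryl-CoA" = -1, "acetate" = -1,
                        "butyrate" = 1, "acetyl-CoA" = 1),
    acetate_kinase = c("acetyl-CoA" = -1, "ADP" = -1, "Pi" = -1,
                       "acetate" = 1, "CoA" = 1, "ATP" = 1),
    acetate_uptake = c("acetate" = -1, "ATP" = -1, "CoA" = -1,
                       "acetyl-CoA" = 1, "ADP" = 1, "Pi" = 1),
    ADHE = c("acetyl-CoA" = -1, "NADH" = -2,
             "ethanol" = 1, "CoA" = 1, "NAD" = 2),
    hydrogenase = c("Fd_red" = -1, "Fd_ox" = 1, "H2" = 1),
    Fd_NAD_oxidoreductase = c("Fd_red" = -1, "NAD" = -1,
                              "Fd_ox" = 1, "NADH" = 1),
    ATP_synthase = c("ADP" = -1, "Pi" = -1, "ATP" = 1, "H2O" = 1),
    ATP_hydrolysis = c("ATP" = -1, "H2O" = -1, "ADP" = 1, "Pi" = 1),
    biomass_sink = c("acetyl-CoA" = -1, "ATP" = -1,
                     "biomass" = 1, "CoA" = 1, "ADP" = 1, "Pi" = 1),
    biomass_e_uptake = c("NADH" = -1, "NAD" = 1, "biomass_e" = 1),
    biomass_e_release = c("NAD" = -1, "biomass_e" = -1, "NADH" = 1)
  )
  species <- sort(unique(unlist(lapply(rxn, names))))
  S <- matrix(0, nrow = length(species), ncol = length(rxn),
              dimnames = list(species, names(rxn)))
  for (r in names(rxn)) S[names(rxn[[r]]), r] <- rxn[[r]]
  idx <- match(species, registry$name)
  if (anyNA(idx)) {
    stop("species missing from registry: ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sp <- registry[idx, c("name", "nC", "gamma", "role")]
  eqs <- vapply(rxn, function(v) {
    lhs <- v[v < 0]; rhs <- v[v > 0]
    paste(paste(sprintf("%g %s", -lhs, names(lhs)), collapse = " + "),
          "->",
          paste(sprintf("%g %s", rhs, names(rhs)), collapse = " + "))
  }, "")
  structure(list(S = S, species = sp,
                 reactions = tibble::tibble(name = names(rxn),
                                            equation = unname(eqs))),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species x %d reactions\n",
              nrow(x$S), ncol(x$S)))
  for (i in seq_len(nrow(x$reactions))) {
    cat(sprintf("  %-22s %s\n", x$reactions$name[i], x$reactions$equation[i]))
  }
  invisible(x)
}

#' Check carbon and electron balance of a reaction
#'
#' Carbon must balance exactly; electrons are checked by
#' degree-of-reduction bookkeeping (each species contributes
#' `coefficient * gamma`; NADH and reduced ferredoxin carry 2 electrons).
#' The `biomass` pseudo-species uses its nominal gamma — its true electron
#' content is adjusted by the `biomass_e` ledger, which is itself checked
#' here.
#'
#' @param reaction named numeric vector of stoichiometric coefficients
#'   (negative = consumed).
#' @param registry metabolite registry.
#' @param tol numeric tolerance.
#' @return list with `carbon_imbalance`, `electron_imbalance`, `balanced`.
#' @export
#' @examples
#' bcd <- c("NADH" = -2, "Fd_ox" = -1, "crotonyl-CoA" = -1,
#'          "NAD" = 2, "Fd_red" = 1, "butyryl-CoA" = 1)
#' check_reaction(bcd)$balanced
check_reaction <- function(reaction, registry = metabolite_registry(),
                           tol = 1e-9) {
  idx <- match(names(reaction), registry$name)
  if (anyNA(idx)) {
    stop("unknown species: ",
         paste(names(reaction)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  carbon <- sum(reaction * registry$nC[idx])
  electrons <- sum(reaction * registry$gamma[idx])
  list(carbon_imbalance = carbon, electron_imbalance = electrons,
       balanced = abs(carbon) < tol && abs(electrons) < tol)
}

#' Fit a nonnegative flux vector to a target exchange stoichiometry
#'
#' Finds reaction rates v >= 0 such that the network's net production of
#' each constrained exchange species equals the target while every internal
#' species and cofactor pool (NAD/NADH, ferredoxin, CoA thioesters, adenine
#' nucleotides) is exactly closed. Exchange species absent from `net` (CO2,
#' H2, H2O, biomass, the biomass electron ledger) are left free. Solved as a
#' nonnegative least-squares problem with heavily weighted closure rows;
#' infeasible targets yield a certificate naming the species that cannot be
#' closed or matched.
#'
#' @param net named numeric vector: target net production (negative =
#'   consumed) over exchange/measured species, in molecule (mmol) units.
#' @param network a [reaction_network()].
#' @param tol relative tolerance on the exchange residual (default 1e-6).
#' @return an object of class `flux_fit`: list with `fluxes` tibble
#'   (reaction, flux), `feasible`, `residual` (relative), `achieved` (net
#'   over all exchange species), and `certificate` (tibble naming violating
#'   species when infeasible).
#' @export
fit_flux <- function(net, network = reaction_network(), tol = 1e-6) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  S <- network$S
  unknown <- setdiff(names(net), rownames(S))
  if (length(unknown)) {
    stop("species not in network: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  closed <- network$species$name[network$species$role %in%
                                   c("internal", "cofactor")]
  closed <- setdiff(closed, names(net))
  W <- 100
  # small ridge keeps the active-set solves nonsingular (the network contains
  # antiparallel reaction pairs, so S has dependent columns)
  ridge <- 1e-3 * diag(ncol(S))
  A <- rbind(W * S[closed, , drop = FALSE], S[names(net), , drop = FALSE],
             ridge)
  b <- c(rep(0, length(closed)), unname(net), rep(0, ncol(S)))
  fit <- pracma::lsqnonneg(A, b)
  v <- setNames(fit$x, colnames(S))
  # polish: re-solve the ridge-free least-squares problem on the active set
  # (minimum-norm via SVD); keep the polished solution if it stays feasible
  active <- which(v > 1e-9)
  if (length(active)) {
    A0 <- rbind(W * S[closed, active, drop = FALSE],
                S[names(net), active, drop = FALSE])
    b0 <- c(rep(0, length(closed)), unname(net))
    sv <- svd(A0)
    pos <- sv$d > max(sv$d) * 1e-10
    x <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b0)) / sv$d[pos])
    if (all(x > -1e-8)) {
      v[] <- 0
      v[active] <- pmax(drop(x), 0)
    }
  }
  achieved_all <- drop(S %*% v)
  scale <- max(sqrt(sum(net^2)), 1)
  ex_resid <- sqrt(sum((achieved_all[names(net)] - net)^2)) / scale
  closure_resid <- abs(achieved_all[closed])
  closure_bad <- closure_resid > 1e-6 * max(1, max(abs(v)))
  feasible <- ex_resid <= tol && !any(closure_bad)
  certificate <- NULL
  if (!feasible) {
    viol <- c(abs(achieved_all[names(net)] - net) / scale,
              closure_resid[closure_bad])
    viol <- sort(viol[viol > tol / 10], decreasing = TRUE)
    certificate <- tibble::tibble(species = names(viol),
                                  violation = unname(viol))
  }
  structure(list(
    fluxes = tibble::tibble(reaction = colnames(S), flux = unname(v)),
    feasible = feasible, residual = ex_resid,
    achieved = achieved_all[network$species$name[
      network$species$role %in% c("measured", "exchange")]],
    closure = achieved_all[closed],
    certificate = certificate, tol = tol
  ), class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit> %s (relative exchange residual %.2e)\n",
              if (x$feasible) "feasible" else "INFEASIBLE", x$residual))
  act <- x$fluxes[x$fluxes$flux > 1e-9, ]
  for (i in seq_len(nrow(act))) {
    cat(sprintf("  %-22s %10.3f\n", act$reaction[i], act$flux[i]))
  }
  if (!is.null(x$certificate)) {
    cat("  unclosable/unmatched species:\n")
    print(x$certificate)
  }
  invisible(x)
}

#' @method tidy flux_fit
#' @export
tidy.flux_fit <- function(x, ...) x$fluxes

#' @method glance flux_fit
#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(feasible = x$feasible, residual = x$residual,
                 n_active = sum(x$fluxes$flux > 1e-9))
}
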