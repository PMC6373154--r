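#' Metabolite registry: carbon counts, molar masses, degrees of reduction
#'
#' Central lookup used by all balance arithmetic. `nC` counts carbon atoms
#' per molecule — for acyl-CoA thioesters only the acyl moiety is counted,
#' with coenzyme A treated as a carbon- and electron-neutral carrier. `gamma`
#' is the degree of reduction (available electrons per molecule, 4C + H - 2O
#' for CHO compounds); NADH and reduced ferredoxin carry 2 electrons each.
#' `biomass` is a pseudo-species (one unit = one acetyl-CoA carbon skeleton,
#' 2 C) whose effective electron content is adjustable through the network's
#' biomass electron-exchange reactions. `biomass_e` is that electron ledger
#' (2 electrons per unit, no carbon).
#'
#' @return a tibble with columns `name`, `nC`, `molar_mass_acid`,
#'   `molar_mass_salt`, `gamma`, `role` (`measured`, `internal`, `cofactor`,
#'   `exchange`).
#' @export
metabolite_registry <- function() {
  tibble::tribble(
    ~name,                  ~nC, ~molar_mass_acid, ~molar_mass_salt, ~gamma, ~role,
    "lactate",                3,            90.08,           112.06,     12, "measured",
    "acetate",                2,            60.05,            82.03,      8, "measured",
    "butyrate",               4,            88.11,               NA,     20, "measured",
    "propionate",             3,            74.08,               NA,     14, "measured",
    "ethanol",                2,            46.07,               NA,     12, "measured",
    "pyruvate",               3,            88.06,               NA,     10, "internal",
    "CO2",                    1,            44.01,               NA,      0, "exchange",
    "H2",                     0,             2.02,               NA,      2, "exchange",
    "H2O",                    0,            18.02,               NA,      0, "exchange",
    "biomass",                2,               NA,               NA,      8, "exchange",
    "biomass_e",              0,               NA,               NA,      2, "exchange",
    "acetyl-CoA",             2,               NA,               NA,      8, "internal",
    "acetoacetyl-CoA",        4,               NA,               NA,     16, "internal",
    "3-hydroxybutyryl-CoA",   4,               NA,               NA,     18, "internal",
    "crotonyl-CoA",           4,               NA,               NA,     18, "internal",
    "butyryl-CoA",            4,               NA,               NA,     20, "internal",
    "CoA",                    0,               NA,               NA,      0, "internal",
    "NAD",                    0,               NA,               NA,      0, "cofactor",
    "NADH",                   0,               NA,               NA,      2, "cofactor",
    "Fd_ox",                  0,               NA,               NA,      0, "cofactor",
    "Fd_red",                 0,               NA,               NA,      2, "cofactor",
    "ATP",                    0,               NA,               NA,      0, "cofactor",
    "ADP",                    0,               NA,               NA,      0, "cofactor",
    "Pi",                     0,               NA,               NA,      0, "cofactor"
  )
}

#' Convert a concentration to millimoles of carbon per litre
#'
#' The common currency of the fermentation balances. `g/L` values are
#' converted to mM through the molar mass of the stated `form` (acid or
#' sodium salt), then multiplied by the carbon count; `mM` values skip the
#' mass step; `mmolC/L` passes through.
#'
#' @param value concentration value(s), >= 0.
#' @param unit `"g/L"`, `"mM"`, or `"mmolC/L"`.
#' @param form `"acid"` or `"salt"` (only consulted for `g/L`).
#' @param metabolite registry name(s).
#' @param registry metabolite registry tibble.
#' @return mmol C per litre (numeric).
#' @export
#' @examples
#' to_mmolC(7.41, "g/L", "salt", "lactate")   # ~198.4
#' to_mmolC(7.00, "g/L", "salt", "acetate")   # ~170.7
to_mmolC <- function(value, unit, form = "acid", metabolite,
                     registry = metabolite_registry()) {
  n <- max(length(value), length(metabolite))
  value <- rep_len(value, n); unit <- rep_len(unit, n)
  form <- rep_len(form, n); metabolite <- rep_len(metabolite, n)
  stopifnot(all(value >= 0))
  idx <- match(metabolite, registry$name)
  if (anyNA(idx)) {
    stop("metabolite(s) not in registry: ",
         paste(unique(metabolite[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    met <- registry[idx[i], ]
    out[i] <- switch(unit[i],
      "mmolC/L" = value[i],
      "mM" = value[i] * met$nC,
      "g/L" = {
        mass <- if (form[i] == "salt") met$molar_mass_salt else met$molar_mass_acid
        if (is.na(mass)) {
          stop("no ", form[i], " molar mass for ", met$name, call. = FALSE)
        }
        value[i] / mass * 1000 * met$nC
      },
      stop("unknown unit '", unit[i], "'", call. = FALSE)
    )
  }
  out
}

#' Net carbon balance of a fermentation
#'
#' Converts a before/after concentration table to mmol C, optionally treats
#' named initial pools as inert background (the yeast-extract-derived
#' butyrate and propionate assumption: their starting amount is subtracted
#' from both phases before netting), and returns per-metabolite net fluxes,
#' the unaccounted residual X (consumed C minus produced C, attributed to
#' biomass and fermentation gases), and substrate utilization percentages.
#' Carbon is conserved by construction:
#' sum(consumed) = sum(produced) + X exactly.
#'
#' @param table tibble with columns `metabolite`, `phase`
#'   (`"before"`/`"after"`), `value`, `unit`, and optionally `form`.
#' @param inert_initial metabolites whose initial pool is assumed
#'   unmetabolized.
#' @param registry metabolite registry.
#' @return an object of class `carbon_balance`: list with `fluxes`
#'   (metabolite, before/after/net mmol C), `consumed_C`, `produced_C`, `X`,
#'   `X_negative` flag, and `utilization` (percent of each consumed
#'   substrate's initial pool used).
#' @export
carbon_balance <- function(table, inert_initial = character(),
                           registry = metabolite_registry()) {
  stopifnot(all(c("metabolite", "phase", "value", "unit") %in% names(table)))
  if (!"form" %in% names(table)) table$form <- "acid"
  if (!all(c("before", "after") %in% table$phase)) {
    stop("table needs both 'before' and 'after' phases", call. = FALSE)
  }
  tab <- table %>%
    dplyr::mutate(mmolC = to_mmolC(.data$value, .data$unit, .data$form,
                                   .data$metabolite, registry)) %>%
    dplyr::group_by(.data$metabolite, .data$phase) %>%
    dplyr::summarise(mmolC = sum(.data$mmolC), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "phase", values_from = "mmolC")
  if (!"before" %in% names(tab)) tab$before <- NA_real_
  if (!"after" %in% names(tab)) tab$after <- NA_real_
  new_after <- is.na(tab$before) & !is.na(tab$after)
  if (any(new_after)) {
    warning("metabolite(s) present only after: ",
            paste(tab$metabolite[new_after], collapse = ", "),
            " (before set to 0)", call. = FALSE)
  }
  tab$before[is.na(tab$before)] <- 0
  tab$after[is.na(tab$after)] <- 0
  inert_amount <- ifelse(tab$metabolite %in% inert_initial, tab$before, 0)
  fluxes <- tab %>%
    dplyr::mutate(before = .data$before - inert_amount,
                  after = .data$after - inert_amount,
                  net = .data$after - .data$before)
  consumed <- sum(-fluxes$net[fluxes$net < 0])
  produced <- sum(fluxes$net[fluxes$net > 0])
  X <- consumed - produced
  utilization <- fluxes %>%
    dplyr::filter(.data$net < 0, .data$before > 0) %>%
    dplyr::transmute(metabolite = .data$metabolite,
                     percent = 100 * (-.data$net) / .data$before)
  structure(list(fluxes = fluxes, consumed_C = consumed,
                 produced_C = produced, X = X, X_negative = X < 0,
                 inert_initial = inert_initial,
                 utilization = utilization),
            class = "carbon_balance")
}

#' @export
print.carbon_balance <- function(x, ...) {
  cat("<carbon_balance> (mmol C)\n")
  print(x$fluxes, n = Inf)
  cat(sprintf("consumed %.1f, produced %.1f, residual X = %.1f%s\n",
              x$consumed_C, x$produced_C, x$X,
              if (x$X_negative) "  [NEGATIVE: more C out than in]" else ""))
  if (nrow(x$utilization)) {
    for (i in seq_len(nrow(x$utilization))) {
      cat(sprintf("  %s utilization: %.1f%%\n",
                  x$utilization$metabolite[i], x$utilization$percent[i]))
    }
  }
  invisible(x)
}

#' @method tidy carbon_balance
#' @export
tidy.carbon_balance <- function(x, ...) {
  dplyr::left_join(x$fluxes,
                   dplyr::rename(x$utilization, utilization_pct = "percent"),
                   by = "metabolite")
}

#' @method glance carbon_balance
#' @export
glance.carbon_balance <- function(x, ...) {
  tibble::tibble(consumed_C = x$consumed_C, produced_C = x$produced_C,
                 X = x$X, X_negative = x$X_negative,
                 n_metabolites = nrow(x$fluxes))
}

#' Round a carbon balance to a display granularity
#'
#' Rounds each net flux (and X) to the nearest multiple of `granularity`
#' (default 10 mmol C) and formats the net equation. The `diagnostics` table
#' records every metabolite whose net was changed by rounding, so that
#' hand-rounded published equations can be compared against the arithmetic
#' result rather than silently reproduced.
#'
#' @param cb a [carbon_balance()] object.
#' @param granularity positive rounding step in mmol C.
#' @return list with `rounded` (metabolite, net, rounded), `X_rounded`,
#'   `equation` (character), and `diagnostics`.
#' @export
round_balance <- function(cb, granularity = 10) {
  stopifnot(granularity > 0)
  rounded <- cb$fluxes %>%
    dplyr::transmute(metabolite = .data$metabolite, net = .data$net,
                     rounded = round(.data$net / granularity) * granularity)
  X_rounded <- round(cb$X / granularity) * granularity
  lhs <- rounded %>% dplyr::filter(.data$rounded < 0)
  rhs <- rounded %>% dplyr::filter(.data$rounded > 0)
  eq <- paste0(
    paste(sprintf("%g %s", -lhs$rounded, lhs$metabolite), collapse = " + "),
    " -> ",
    paste(c(sprintf("%g %s", rhs$rounded, rhs$metabolite),
            sprintf("%g X", X_rounded)), collapse = " + "))
  diagnostics <- rounded %>%
    dplyr::filter(abs(.data$net - .data$rounded) > 1e-9) %>%
    dplyr::mutate(delta = .data$rounded - .data$net)
  list(rounded = rounded, X_rounded = X_rounded, equation = eq,
       diagnostics = diagnostics, granularity = granularity)
}
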