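#' Default context-to-reaction grouping
#'
#' Maps neighbourhood context labels to the two reaction groups: markers of
#' butyryl-CoA formation (3-hydroxybutyryl-CoA / acyl-CoA dehydrogenase
#' neighbourhoods) versus lactate oxidation (GlcD and/or LldP
#' neighbourhoods).
#'
#' @return named list of context label vectors (`lactate`, `butyrate`).
#' @export
context_groups <- function() {
  list(lactate = c("GlcD", "LldP_GlcD"),
       butyrate = c("3-hydroxybutyryl-CoA", "acyl-CoA"))
}

#' Do reaction-context groups form separate clades?
#'
#' Tests the headline claim that Etf complexes cluster by catalysed reaction
#' rather than by species: for each of two disjoint context groups it checks
#' whether the group's tips form a rooted clade, extracts that node's
#' bootstrap support, and — when monophyly fails — lists the intruding
#' ("breaker") tips found under the group's most recent common ancestor.
#'
#' @param tree an `ape::phylo` (ideally a [bootstrap_support()] tree).
#' @param labels tibble with columns `tip`, `context`, `species` covering
#'   every tip.
#' @param groups named list of two context-label vectors (default
#'   [context_groups()]). Contexts outside both groups are ignored.
#' @return an object of class `separation_report`: list with `groups` (a
#'   tibble: group, n_tips, is_clade, support, breakers list-column) and
#'   `species_mixing`, the number of species contributing tips to both
#'   groups (high mixing plus clean separation is the cross-feeding
#'   signature).
#' @export
separation_report <- function(tree, labels, groups = context_groups()) {
  stopifnot(length(groups) == 2L, !is.null(names(groups)))
  if (length(intersect(groups[[1]], groups[[2]]))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing_tips <- setdiff(tree$tip.label, labels$tip)
  if (length(missing_tips)) {
    stop("tips without labels: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  lab <- labels[match(tree$tip.label, labels$tip), ]
  rows <- purrr::map_dfr(names(groups), function(g) {
    tips <- lab$tip[lab$context %in% groups[[g]]]
    if (length(tips) == 0L) stop("group '", g, "' has no tips", call. = FALSE)
    cs <- clade_support(tree, tips)
    breakers <- character()
    if (!cs$present && length(tips) >= 2L) {
      mrca <- ape::getMRCA(tree, tips)
      below <- tree_clades(tree)[[as.character(mrca)]]
      breakers <- setdiff(below, tips)
    }
    tibble::tibble(group = g, n_tips = length(tips), is_clade = cs$present,
                   support = cs$support, breakers = list(breakers))
  })
  mixing <- lab %>%
    dplyr::filter(.data$context %in% unlist(groups)) %>%
    dplyr::mutate(grp = ifelse(.data$context %in% groups[[1]],
                               names(groups)[1], names(groups)[2])) %>%
    dplyr::distinct(.data$species, .data$grp) %>%
    dplyr::count(.data$species) %>%
    dplyr::filter(.data$n == 2L) %>%
    nrow()
  structure(list(groups = rows, species_mixing = mixing,
                 group_spec = groups),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report>\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %s: %d tips, %s%s%s\n", g$group, g$n_tips,
                if (g$is_clade) "monophyletic" else "NOT monophyletic",
                if (!is.na(g$support)) sprintf(", support %.1f%%", g$support) else "",
                if (length(g$breakers[[1]]))
                  paste0(", breakers: ", paste(g$breakers[[1]], collapse = ", "))
                else ""))
  }
  cat("  species contributing tips to both groups:", x$species_mixing, "\n")
  invisible(x)
}

#' @method tidy separation_report
#' @export
tidy.separation_report <- function(x, ...) x$groups

#' @method glance separation_report
#' @export
glance.separation_report <- function(x, ...) {
  tibble::tibble(
    both_clades = all(x$groups$is_clade),
    min_support = suppressWarnings(min(x$groups$support, na.rm = TRUE)),
    n_breakers = sum(lengths(x$groups$breakers)),
    species_mixing = x$species_mixing
  )
}

#' Within-context versus within-species mean distances
#'
#' Quantifies the observation that Etf subunits catalysing the same reaction
#' in different species resemble each other more than the different Etf
#' paralogs within one species: computes the mean distance over pairs sharing
#' a context but not a species, and over pairs sharing a species but not a
#' context. The cross-feeding claim holds when the first mean is smaller.
#'
#' @param d symmetric distance matrix whose dimnames are tip ids.
#' @param labels tibble with columns `tip`, `context`, `species`.
#' @return one-row tibble: `within_context_between_species`,
#'   `within_species_between_context`, `difference`, `claim_holds`.
#' @export
cross_species_similarity <- function(d, labels) {
  tips <- rownames(d)
  if (!all(tips %in% labels$tip)) {
    stop("distance matrix labels missing from label table", call. = FALSE)
  }
  lab <- labels[match(tips, labels$tip), ]
  n <- length(tips)
  ij <- which(upper.tri(d), arr.ind = TRUE)
  same_ctx <- lab$context[ij[, 1]] == lab$context[ij[, 2]]
  same_sp <- lab$species[ij[, 1]] == lab$species[ij[, 2]]
  dv <- d[upper.tri(d)]
  wc <- dv[same_ctx & !same_sp]
  ws <- dv[same_sp & !same_ctx]
  if (length(wc) == 0L && length(ws) == 0L) {
    stop("no informative pairs: every context/species combination is degenerate",
         call. = FALSE)
  }
  m1 <- if (length(wc)) mean(wc) else NA_real_
  m2 <- if (length(ws)) mean(ws) else NA_real_
  tibble::tibble(
    within_context_between_species = m1,
    within_species_between_context = m2,
    difference = m1 - m2,
    claim_holds = !is.na(m1) && !is.na(m2) && m1 < m2
  )
}
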