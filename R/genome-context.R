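#' Detect etfA/etfB gene clusters and classify their neighbourhood context
#'
#' Pairs co-located EtfA and EtfB homology hits (same replicon, at most
#' `max_gap_genes` intervening genes, strand unconstrained), collects the
#' coding genes within `window` genes on either side, and assigns a context
#' label from the marker hits found in that neighbourhood:
#'
#' * lactate markers (`LldP`, `GlcD`) and butyrate markers
#'   (`3-hydroxybutyryl-CoA`, `acyl-CoA` dehydrogenases) both present ->
#'   `"ambiguous"`;
#' * within lactate markers: LldP + GlcD -> `"LldP_GlcD"`, GlcD alone ->
#'   `"GlcD"` (LldP without the FAD oxidoreductase stays `"unassigned"`);
#' * within butyrate markers: 3-hydroxybutyryl-CoA dehydrogenase dominates
#'   acyl-CoA dehydrogenase;
#' * no marker in the window -> `"unassigned"`.
#'
#' @param annotation gene-record tibble ([read_annotation()]).
#' @param etf_hits [find_homologs()] output for the EtfA/EtfB queries;
#'   `query_id` (after `query_class` mapping) must be `"etfA"` or `"etfB"`.
#' @param marker_hits [find_homologs()] output for the marker queries;
#'   mapped classes must be among `"GlcD"`, `"LldP"`,
#'   `"3-hydroxybutyryl-CoA"`, `"acyl-CoA"`.
#' @param window number of coding genes scanned on each side of the pair
#'   (default 5).
#' @param max_gap_genes maximum intervening genes between etfA and etfB
#'   (default 1).
#' @param query_class optional named character vector mapping `query_id`
#'   values to classes; by default the `query_id` is the class.
#' @return a tibble of clusters (class `etf_clusters`) in genome order:
#'   `replicon_id`, `etfA_locus`, `etfB_locus`, `context`, `start`, `end`,
#'   `neighbors` (list-column of locus tags). Unpairable Etf hits are kept in
#'   attribute `unpaired` (tibble: locus_tag, subunit), not as clusters.
#' @export
detect_etf_clusters <- function(annotation, etf_hits, marker_hits,
                                window = 5, max_gap_genes = 1,
                                query_class = NULL) {
  map_class <- function(q) {
    if (is.null(query_class)) q else unname(query_class[q])
  }
  ann <- annotation %>%
    dplyr::group_by(.data$replicon_id) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::mutate(gene_index = dplyr::row_number()) %>%
    dplyr::ungroup()

  etf <- etf_hits %>%
    dplyr::mutate(class = map_class(.data$query_id)) %>%
    dplyr::filter(.data$class %in% c("etfA", "etfB")) %>%
    dplyr::distinct(.data$locus_tag, .data$class) %>%
    dplyr::inner_join(ann, by = "locus_tag")
  marker_classes <- c("GlcD", "LldP", "3-hydroxybutyryl-CoA", "acyl-CoA")
  markers <- marker_hits %>%
    dplyr::mutate(class = map_class(.data$query_id)) %>%
    dplyr::filter(.data$class %in% marker_classes) %>%
    dplyr::distinct(.data$locus_tag, .data$class)

  clusters <- list()
  unpaired <- list()
  for (rep_id in unique(ann$replicon_id)) {
    a_idx <- etf %>% dplyr::filter(.data$replicon_id == rep_id,
                                   .data$class == "etfA")
    b_idx <- etf %>% dplyr::filter(.data$replicon_id == rep_id,
                                   .data$class == "etfB")
    used_b <- integer()
    for (k in seq_len(nrow(a_idx))) {
      ai <- a_idx$gene_index[k]
      cand <- b_idx %>%
        dplyr::filter(!.data$gene_index %in% used_b,
                      .data$gene_index != ai,
                      abs(.data$gene_index - ai) <= max_gap_genes + 1L) %>%
        dplyr::arrange(abs(.data$gene_index - ai),
                       dplyr::desc(.data$gene_index > ai))
      if (nrow(cand) == 0L) {
        unpaired[[length(unpaired) + 1L]] <-
          tibble::tibble(locus_tag = a_idx$locus_tag[k], subunit = "etfA")
        next
      }
      b <- cand[1L, ]
      used_b <- c(used_b, b$gene_index)
      lo <- min(ai, b$gene_index); hi <- max(ai, b$gene_index)
      nb <- ann %>%
        dplyr::filter(.data$replicon_id == rep_id,
                      .data$gene_index >= lo - window,
                      .data$gene_index <= hi + window,
                      !.data$gene_index %in% c(ai, b$gene_index))
      present <- markers$class[markers$locus_tag %in% nb$locus_tag]
      clusters[[length(clusters) + 1L]] <- tibble::tibble(
        replicon_id = rep_id,
        etfA_locus = a_idx$locus_tag[k],
        etfB_locus = b$locus_tag,
        context = classify_context(present),
        start = min(a_idx$start[k], b$start),
        end = max(a_idx$end[k], b$end),
        neighbors = list(nb$locus_tag)
      )
    }
    leftover_b <- b_idx %>% dplyr::filter(!.data$gene_index %in% used_b)
    if (nrow(leftover_b)) {
      unpaired[[length(unpaired) + 1L]] <-
        tibble::tibble(locus_tag = leftover_b$locus_tag, subunit = "etfB")
    }
  }
  out <- if (length(clusters)) {
    dplyr::bind_rows(clusters) %>%
      dplyr::arrange(.data$replicon_id, .data$start)
  } else {
    tibble::tibble(replicon_id = character(), etfA_locus = character(),
                   etfB_locus = character(), context = character(),
                   start = integer(), end = integer(), neighbors = list())
  }
  attr(out, "unpaired") <- if (length(unpaired)) {
    dplyr::bind_rows(unpaired)
  } else {
    tibble::tibble(locus_tag = character(), subunit = character())
  }
  class(out) <- c("etf_clusters", class(out))
  out
}

classify_context <- function(marker_classes) {
  lactate <- intersect(marker_classes, c("GlcD", "LldP"))
  butyrate <- intersect(marker_classes, c("3-hydroxybutyryl-CoA", "acyl-CoA"))
  has_lactate_ctx <- "GlcD" %in% lactate
  if (length(butyrate) && (has_lactate_ctx || length(lactate))) {
    return("ambiguous")
  }
  if (has_lactate_ctx) {
    return(if ("LldP" %in% lactate) "LldP_GlcD" else "GlcD")
  }
  if ("3-hydroxybutyryl-CoA" %in% butyrate) return("3-hydroxybutyryl-CoA")
  if ("acyl-CoA" %in% butyrate) return("acyl-CoA")
  "unassigned"
}

#' @export
print.etf_clusters <- function(x, ...) {
  cat(sprintf("<etf_clusters> %d cluster(s), %d unpaired Etf hit(s)\n",
              nrow(x), nrow(attr(x, "unpaired"))))
  NextMethod()
}

#' Serialise detected clusters
#'
#' @param clusters an `etf_clusters` tibble.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return the cluster tibble, invisibly.
#' @export
write_clusters <- function(clusters, tsv_path = NULL, json_path = NULL) {
  flat <- clusters %>%
    dplyr::mutate(neighbors = purrr::map_chr(.data$neighbors, paste,
                                             collapse = ","))
  if (!is.null(tsv_path)) {
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(clusters)
}
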