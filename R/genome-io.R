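#' Read an annotated genome into a gene-record tibble
#'
#' Coding features become one row per CDS with 1-based inclusive coordinates
#' (GenBank convention) preserved from the source; reverse-strand proteins
#' are translated in reading-frame direction. The GenBank reader is a
#' minimal flat-file parser (LOCUS / FEATURES / CDS / ORIGIN); GFF3 goes
#' through rtracklayer and requires the companion FASTA to translate CDS
#' features.
#'
#' @param path GenBank flat file or GFF3 file.
#' @param format `"genbank"` or `"gff3"` (guessed from the extension when
#'   missing).
#' @param fasta genome FASTA path (required for `format = "gff3"`).
#' @return a tibble with columns `locus_tag`, `replicon_id`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `product`, `protein`; sorted by replicon then
#'   start; attribute `replicon_length` holds named replicon lengths. CDS
#'   without a translatable sequence are skipped with a warning.
#' @export
read_annotation <- function(path, format = NULL, fasta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "genbank"
    }
  }
  format <- match.arg(format, c("genbank", "gff3"))
  ann <- if (format == "genbank") {
    read_genbank(path)
  } else {
    if (is.null(fasta)) stop("gff3 input needs the companion FASTA",
                             call. = FALSE)
    read_gff3_fasta(path, fasta)
  }
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (any(ann$start > ann$end)) {
    bad <- ann$locus_tag[ann$start > ann$end][1]
    stop("malformed record ", bad, ": start > end", call. = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (anyDuplicated(ann$locus_tag)) {
    stop("duplicate locus_tag: ",
         ann$locus_tag[duplicated(ann$locus_tag)][1], call. = FALSE)
  }
  empty <- !nzchar(ann$protein) | is.na(ann$protein)
  if (any(empty)) {
    warning(sum(empty), " CDS without translatable sequence skipped",
            call. = FALSE)
    ann <- ann[!empty, ]
  }
  lens <- attr(ann, "replicon_length")
  out <- dplyr::arrange(ann, .data$replicon_id, .data$start)
  attr(out, "replicon_length") <- lens
  out
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_breaks <- c(0L, which(lines == "//"))
  records <- purrr::map(seq_len(length(rec_breaks) - 1L), function(k) {
    lines[(rec_breaks[k] + 1L):(rec_breaks[k + 1L] - 1L)]
  })
  records <- purrr::keep(records, ~ any(grepl("^LOCUS", .x)))
  lens <- c()
  rows <- purrr::map_dfr(records, function(rec) {
    locus_line <- rec[grepl("^LOCUS", rec)][1]
    fields <- strsplit(trimws(sub("^LOCUS", "", locus_line)), "\\s+")[[1]]
    replicon <- fields[1]
    lens[replicon] <<- suppressWarnings(as.integer(fields[2]))
    feat_start <- which(grepl("^FEATURES", rec))
    origin_at <- which(grepl("^ORIGIN", rec))
    seq_dna <- NA_character_
    if (length(origin_at)) {
      body <- rec[seq.int(origin_at[1] + 1L, length(rec))]
      seq_dna <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    if (!length(feat_start)) return(NULL)
    feat_end <- if (length(origin_at)) origin_at[1] - 1L else length(rec)
    feats <- rec[seq.int(feat_start[1] + 1L, feat_end)]
    # feature keys start at column 6; qualifiers are further indented
    is_key <- grepl("^     \\S", feats)
    key_idx <- which(is_key)
    purrr::map_dfr(seq_along(key_idx), function(f) {
      first <- feats[key_idx[f]]
      key <- sub("^\\s*(\\S+).*", "\\1", first)
      if (key != "CDS") return(NULL)
      last <- if (f < length(key_idx)) key_idx[f + 1L] - 1L else length(feats)
      block <- feats[key_idx[f]:last]
      loc <- sub("^\\s*CDS\\s+", "", block[1])
      qual_text <- paste(trimws(block[-1]), collapse = "\n")
      parse_genbank_cds(loc, qual_text, replicon, seq_dna)
    })
  })
  attr(rows, "replicon_length") <- lens
  rows
}

parse_genbank_cds <- function(loc, qual_text, replicon, seq_dna) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 2L || anyNA(nums)) {
    stop("unparseable CDS location '", loc, "' in ", replicon, call. = FALSE)
  }
  start <- nums[1]; end <- nums[2]
  grab <- function(q) {
    m <- regmatches(qual_text,
                    regexpr(paste0("/", q, '="[^"]*"'), qual_text))
    if (!length(m)) return(NA_character_)
    gsub("\\s+", " ", sub('"$', "", sub(paste0("^/", q, '="'), "", m)))
  }
  locus_tag <- grab("locus_tag")
  product <- grab("product")
  translation <- grab("translation")
  if (!is.na(translation)) translation <- gsub(" ", "", translation)
  if (is.na(translation) && !is.na(seq_dna) && start <= end &&
      end <= nchar(seq_dna)) {
    translation <- translate_cds(substr(seq_dna, start, end), strand)
  }
  tibble::tibble(
    locus_tag = locus_tag %||% NA_character_,
    replicon_id = replicon,
    start = start, end = end, strand = strand,
    product = product,
    protein = translation %||% NA_character_
  )
}

translate_cds <- function(dna, strand) {
  d <- Biostrings::DNAString(dna)
  if (strand == "-") d <- Biostrings::reverseComplement(d)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(d, if.fuzzy.codon = "solve")))
  sub("\\*$", "", aa)
}

read_gff3_fasta <- function(path, fasta) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop("unreadable GFF3 file ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  gr <- gr[gr$type == "CDS"]
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  meta <- as.data.frame(gr)
  get_col <- function(nm, fallback) {
    if (nm %in% names(meta)) as.character(meta[[nm]]) else fallback
  }
  locus <- get_col("locus_tag", get_col("ID", NA_character_))
  rows <- tibble::tibble(
    locus_tag = locus,
    replicon_id = as.character(meta$seqnames),
    start = meta$start, end = meta$end,
    strand = as.character(meta$strand),
    product = get_col("product", NA_character_),
    protein = NA_character_
  )
  rows$protein <- purrr::pmap_chr(
    rows[, c("replicon_id", "start", "end", "strand")],
    function(replicon_id, start, end, strand) {
      if (!replicon_id %in% names(genome)) return(NA_character_)
      translate_cds(as.character(
        Biostrings::subseq(genome[[replicon_id]], start, end)), strand)
    })
  attr(rows, "replicon_length") <-
    setNames(Biostrings::width(genome), names(genome))
  rows
}

#' Write a gene-record tibble as a GenBank flat file
#'
#' @param annotation tibble as produced by [read_annotation()].
#' @param sequences named character vector of replicon DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(annotation, sequences, path) {
  out <- character()
  for (rep_id in names(sequences)) {
    dna <- sequences[[rep_id]]
    out <- c(out,
             sprintf("LOCUS       %-16s %d bp    DNA     circular BCT 01-JAN-2024",
                     rep_id, nchar(dna)),
             sprintf("DEFINITION  synthetic replicon %s.", rep_id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", nchar(dna)))
    sub_ann <- annotation[annotation$replicon_id == rep_id, ]
    for (i in seq_len(nrow(sub_ann))) {
      g <- sub_ann[i, ]
      loc <- sprintf("%d..%d", g$start, g$end)
      if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
      tr <- paste0('"', g$protein, '"')
      chunks <- substring(tr, seq(1, nchar(tr), 44),
                          pmin(seq(1, nchar(tr), 44) + 43, nchar(tr)))
      out <- c(out,
               sprintf("     CDS             %s", loc),
               sprintf('                     /locus_tag="%s"', g$locus_tag),
               sprintf('                     /product="%s"', g$product),
               paste0("                     /translation=", chunks[1]),
               if (length(chunks) > 1)
                 paste0("                     ", chunks[-1]))
    }
    out <- c(out, "ORIGIN")
    starts <- seq(1, nchar(dna), 60)
    for (s in starts) {
      seg <- substr(dna, s, min(s + 59, nchar(dna)))
      blocks <- substring(seg, seq(1, nchar(seg), 10),
                          pmin(seq(1, nchar(seg), 10) + 9, nchar(seg)))
      out <- c(out, sprintf("%9d %s", s,
                            paste(tolower(blocks), collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a gene-record tibble as GFF3 plus genome FASTA
#'
#' @inheritParams write_genbank
#' @param gff_path,fasta_path output paths.
#' @return `gff_path`, invisibly.
#' @export
write_gff3 <- function(annotation, sequences, gff_path, fasta_path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(sequences),
                     nchar(sequences)))
  feat <- sprintf(
    "%s\tetfcrossfeed\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s;product=%s",
    annotation$replicon_id, annotation$start, annotation$end,
    annotation$strand, annotation$locus_tag, annotation$locus_tag,
    gsub("[;=\t]", " ", annotation$product))
  writeLines(c(lines, feat), gff_path)
  write_dna_fasta(sequences, fasta_path)
  invisible(gff_path)
}

write_dna_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
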