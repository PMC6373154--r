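# Independent brute-force oracles for alignment scores, written as top-down
# recursions over (prefix, prefix, previous-column-state). They share only
# the scoring *definition* with the package (gap of length L costs
# open + L * extend), never its implementation.

oracle_matrix <- function(name) {
  if (name == "id") {
    aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
    S <- diag(1, 21)
    dimnames(S) <- list(aa, aa)
    S
  } else {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
    S <- e$BLOSUM62[aa, aa]
    storage.mode(S) <- "double"
    S
  }
}

# Best global alignment score of a[1..i] vs b[1..j] whose last column is in
# `state` ("m" = residue pair, "x" = gap in b, "y" = gap in a).
oracle_global <- function(a, b, S, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i == 0 && j == 0) {
      return(if (state == "start") 0 else -Inf)
    }
    if (i < 0 || j < 0) return(-Inf)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- switch(state,
      "m" = {
        if (i == 0 || j == 0) -Inf
        else S[ca[i], cb[j]] +
          max(rec(i - 1, j - 1, "m"), rec(i - 1, j - 1, "x"),
              rec(i - 1, j - 1, "y"), rec(i - 1, j - 1, "start"))
      },
      "x" = {
        if (i == 0) -Inf
        else max(rec(i - 1, j, "m") - open - ext,
                 rec(i - 1, j, "x") - ext,
                 rec(i - 1, j, "y") - open - ext,
                 rec(i - 1, j, "start") - open - ext)
      },
      "y" = {
        if (j == 0) -Inf
        else max(rec(i, j - 1, "m") - open - ext,
                 rec(i, j - 1, "y") - ext,
                 rec(i, j - 1, "x") - open - ext,
                 rec(i, j - 1, "start") - open - ext)
      },
      "start" = -Inf
    )
    memo[[key]] <- val
    val
  }
  n <- length(ca); m <- length(cb)
  max(rec(n, m, "m"), rec(n, m, "x"), rec(n, m, "y"))
}

# Local score = best global score over all substring pairs (0 if none
# positive). Exhaustive over substrings; use only on short strings.
oracle_local <- function(a, b, S, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(ca)) for (i2 in i1:length(ca)) {
    sub_a <- paste(ca[i1:i2], collapse = "")
    for (j1 in seq_along(cb)) for (j2 in j1:length(cb)) {
      sub_b <- paste(cb[j1:j2], collapse = "")
      best <- max(best, oracle_global(sub_a, sub_b, S, open, ext))
    }
  }
  best
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Brute-force per-pair p-distance by explicit site counting.
oracle_p_distance <- function(rows) {
  mats <- strsplit(rows, "")
  n <- length(rows)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ri <- mats[[i]]; rj <- mats[[j]]
    ok <- ri != "-" & rj != "-"
    d[i, j] <- d[j, i] <- sum(ri[ok] != rj[ok]) / sum(ok)
  }
  d
}

# Build the published-style concentration tables (values already in mmol C).
eq1_table <- function() {
  tibble::tibble(
    metabolite = c("acetate", "lactate", "propionate", "butyrate",
                   "acetate", "lactate", "propionate", "butyrate", "ethanol"),
    phase = c(rep("before", 4), rep("after", 5)),
    value = c(170, 200, 3, 18, 76, 4, 3, 190, 29),
    unit = "mmolC/L"
  )
}

eq2_table <- function() {
  tibble::tibble(
    metabolite = c("acetate", "lactate", "butyrate", "ethanol"),
    phase = c("before", "before", "after", "after"),
    value = c(100, 200, 170, 30),
    unit = "mmolC/L"
  )
}
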