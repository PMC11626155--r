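## ---------------------------------------------------------------------------
## Haplotype -> paternal-ancestry predictors
## ---------------------------------------------------------------------------

#' Derive haplotype-to-ancestry predictor signatures
#'
#' Scans a haplotype frequency table restricted to the signature-defining
#' reference groups (classically: Arabian, Thoroughbred, Coldblood, Spanish,
#' WestAsian). A haplotype observed at least `min_count` times in exactly one
#' reference group becomes a unique predictor of that ancestry; in two or
#' more, a `varied` predictor listing the groups (joined with `"/"`); in
#' none, `unexplained`. Curated overrides (named character vector
#' `ht -> signature`) are applied last and logged as such — they are the
#' mechanism for reproducing expert-curated predictor lists that mix
#' frequency evidence with narrative breed history.
#'
#' @param freq an `ht_freq_table` (from [ht_frequencies()]).
#' @param reference_groups character vector of reference group column names.
#' @param min_count minimum within-group count for a haplotype to count as
#'   observed in that group (default 2; a single observation is weak
#'   evidence).
#' @param curated optional named character vector of overrides.
#' @return `data.frame` of class `signature_map` with columns `ht`,
#'   `signature`, `provenance` (`"frequency"` or `"curated"`).
#' @export
derive_predictors <- function(freq, reference_groups, min_count = 2L,
                              curated = NULL) {
  stopifnot(inherits(freq, "ht_freq_table"), min_count >= 1L)
  absent <- setdiff(reference_groups, colnames(freq$counts))
  if (length(absent)) {
    stop("reference group(s) absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  C <- freq$counts[, reference_groups, drop = FALSE]
  sig <- apply(C, 1L, function(row) {
    hit <- reference_groups[row >= min_count]
    if (length(hit) == 0L) "unexplained"
    else paste(hit, collapse = "/")
  })
  out <- data.frame(ht = rownames(C), signature = unname(sig),
                    provenance = "frequency", stringsAsFactors = FALSE)
  if (!is.null(curated) && length(curated)) {
    for (ht in names(curated)) {
      if (ht %in% out$ht) {
        out$signature[out$ht == ht] <- curated[[ht]]
        out$provenance[out$ht == ht] <- "curated"
      } else {
        out <- rbind(out, data.frame(ht = ht, signature = curated[[ht]],
                                     provenance = "curated",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("signature_map", "data.frame")
  out
}

# Default grouping of signatures into historical bases.
default_recent_groups <- c("Arabian", "Thoroughbred", "Coldblood")
default_early_groups <- c("Spanish", "WestAsian")

signature_basis <- function(signature, recent_groups, early_groups) {
  vapply(signature, function(s) {
    if (is.na(s) || s == "unexplained") return("unexplained")
    if (grepl("/", s, fixed = TRUE)) return("varied")
    if (s %in% recent_groups) return("recent_breeding")
    if (s %in% early_groups) return("early_dissemination")
    "unexplained"
  }, character(1), USE.NAMES = FALSE)
}

#' Classify samples by paternal-ancestry signature
#'
#' Deterministic lookup of each assignment's haplotype label in a signature
#' map. Non-Crown assignments get basis `non_crown`; Crown haplotypes carry
#' basis `recent_breeding` (Arabian/Thoroughbred/Coldblood signatures),
#' `early_dissemination` (Spanish/WestAsian), `varied`, or `unexplained`.
#'
#' @param assignments `ht_assignments` data.frame from [batch_call()].
#' @param map a `signature_map` from [derive_predictors()].
#' @param tree the `backbone_tree` (Crown membership).
#' @param recent_groups,early_groups signature names contributing to the
#'   recent-breeding and early-dissemination bases.
#' @return `data.frame` of class `ancestry_calls` with columns `sample`,
#'   `label`, `signature`, `basis`.
#' @export
classify_samples <- function(assignments, map, tree,
                             recent_groups = default_recent_groups,
                             early_groups = default_early_groups) {
  labels <- assignment_labels(assignments)
  nodes <- assignment_nodes(assignments)
  lut <- stats::setNames(map$signature, map$ht)
  signature <- unname(lut[labels])
  signature[is.na(signature)] <- "unexplained"
  basis <- signature_basis(signature, recent_groups, early_groups)
  crown <- bt_in_crown(tree, nodes)
  basis[!crown] <- "non_crown"
  signature[!crown] <- "non_crown"
  out <- data.frame(sample = names(labels), label = unname(labels),
                    signature = signature, basis = basis,
                    stringsAsFactors = FALSE)
  class(out) <- c("ancestry_calls", "data.frame")
  out
}

#' Ancestry composition per group
#'
#' Counts and one-decimal percentages of ancestry calls per group, both at
#' the basis level (recent breeding / early dissemination / varied /
#' unexplained / non-Crown) and at the signature level. Every call lands in
#' exactly one bucket, so per-group counts sum to the group size.
#'
#' @param calls an `ancestry_calls` data.frame from [classify_samples()].
#' @param grouping named character vector, sample -> group (region/breed).
#' @return list of class `ancestry_composition` with `by_basis` and
#'   `by_signature` long-format data.frames (`group`, `category`, `n`,
#'   `pct`).
#' @export
summarize_composition <- function(calls, grouping) {
  missing <- setdiff(calls$sample, names(grouping))
  if (length(missing)) {
    stop("samples missing from grouping: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grp <- grouping[calls$sample]
  tab <- function(category) {
    t0 <- table(grp, category)
    df <- as.data.frame(t0, stringsAsFactors = FALSE)
    names(df) <- c("group", "category", "n")
    tot <- stats::setNames(as.integer(table(grp)), names(table(grp)))
    df$pct <- round(100 * df$n / tot[df$group], 1)
    df[order(df$group, df$category), c("group", "category", "n", "pct")]
  }
  out <- list(by_basis = tab(calls$basis),
              by_signature = tab(calls$signature))
  rownames(out$by_basis) <- rownames(out$by_signature) <- NULL
  class(out) <- "ancestry_composition"
  out
}

#' @export
print.ancestry_composition <- function(x, ...) {
  cat("ancestry composition (by basis):\n")
  print.data.frame(x$by_basis)
  invisible(x)
}
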