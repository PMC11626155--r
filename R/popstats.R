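## ---------------------------------------------------------------------------
## Haplotype frequency spectra and Nei diversity
## ---------------------------------------------------------------------------

# Pull a sample -> label vector out of the accepted assignment shapes.
assignment_labels <- function(assignments) {
  if (inherits(assignments, "ht_assignments") || is.data.frame(assignments)) {
    df <- assignments
    if ("ok" %in% names(df)) df <- df[df$ok, , drop = FALSE]
    stats::setNames(df$label, df$sample)
  } else if (is.character(assignments)) {
    if (is.null(names(assignments))) {
      stop("label vector must be named by sample", call. = FALSE)
    }
    assignments
  } else {
    stop("unsupported assignments object", call. = FALSE)
  }
}

assignment_nodes <- function(assignments) {
  if (inherits(assignments, "ht_assignments") || is.data.frame(assignments)) {
    df <- assignments
    if ("ok" %in% names(df)) df <- df[df$ok, , drop = FALSE]
    stats::setNames(df$node, df$sample)
  } else {
    stop("node lookup needs a batch_call() result", call. = FALSE)
  }
}

#' Haplotype frequency table by group
#'
#' Direct counting of haplotype labels per group. Terminal HTs and inner-node
#' `"*"` labels are distinct rows. Empty groups present in the grouping get a
#' zero column with undefined (NaN) frequencies, flagged in `empty_groups`.
#'
#' @param assignments `ht_assignments` data.frame (failed calls excluded) or
#'   a named sample -> label character vector.
#' @param grouping named character vector, sample -> group.
#' @return object of class `ht_freq_table`: `counts` (label x group integer
#'   matrix), `freq` (column frequencies), `n` (column totals),
#'   `empty_groups`.
#' @export
ht_frequencies <- function(assignments, grouping) {
  labels <- assignment_labels(assignments)
  missing <- setdiff(names(labels), names(grouping))
  if (length(missing)) {
    stop("samples missing from grouping: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- sort(unique(unname(grouping)))
  lev <- sort(unique(unname(labels)))
  counts <- table(factor(labels, levels = lev),
                  factor(grouping[names(labels)], levels = groups))
  counts <- matrix(as.integer(counts), nrow = length(lev),
                   dimnames = list(lev, groups))
  n <- colSums(counts)
  freq <- sweep(counts, 2L, n, "/")
  structure(list(counts = counts, freq = freq, n = n,
                 empty_groups = names(n)[n == 0L]),
            class = "ht_freq_table")
}

#' @export
print.ht_freq_table <- function(x, ...) {
  cat(sprintf("ht_freq_table: %d haplotype(s) x %d group(s), %d sample(s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$n)))
  if (length(x$empty_groups)) {
    cat("  empty group(s):", paste(x$empty_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Heatmap of haplotype frequencies by group
#'
#' Base-graphics rendering of the frequency table (groups on x, haplotypes on
#' y, shading by within-group frequency).
#'
#' @param x an `ht_freq_table`.
#' @param ... passed to [graphics::image()].
#' @export
plot.ht_freq_table <- function(x, ...) {
  f <- x$freq
  f[is.nan(f)] <- 0
  op <- graphics::par(mar = c(6, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(f)), seq_len(nrow(f)), t(f),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(f)), labels = colnames(f), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(f)), labels = rownames(f), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Nei haplotype diversity with standard deviation
#'
#' Unbiased estimator `Hd = n (1 - sum p_i^2) / (n - 1)` — the probability
#' that two samples drawn without replacement carry different haplotypes —
#' with the matching sampling variance
#' `V = 2/(n(n-1)) * { 2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2 }`
#' and `SD = sqrt(V)` (Nei 1987).
#'
#' @param counts non-negative integer vector of haplotype counts (named or
#'   not); total must be at least 2.
#' @return object of class `diversity_result`: `Hd`, `SD`, `n`, `k` (number
#'   of distinct haplotypes observed).
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 2) {
    stop(msy_condition("msy_undefined_diversity",
                       "haplotype diversity undefined for n < 2"))
  }
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  Hd <- n * (1 - s2) / (n - 1)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  structure(list(Hd = Hd, SD = sqrt(max(V, 0)), n = n,
                 k = sum(counts > 0)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Hd = %.3f (SD %.3f), n = %d, k = %d haplotypes\n",
              x$Hd, x$SD, x$n, x$k))
  invisible(x)
}

#' Per-group descriptive summary of haplotype composition
#'
#' One row per group plus a Total row: sample counts inside/outside the
#' Crown, distinct haplotype counts (all / Crown / non-Crown), and Nei
#' diversity (with SD) for the Crown subset and for all samples. Diversity is
#' `NA` where fewer than two samples are available.
#'
#' @param assignments `ht_assignments` data.frame from [batch_call()].
#' @param grouping named character vector, sample -> group.
#' @param tree the `backbone_tree` (supplies Crown membership per node).
#' @return `data.frame` with columns `group`, `n`, `n_crown`, `n_noncrown`,
#'   `ht_total`, `ht_crown`, `ht_noncrown`, `hd_crown`, `sd_crown`, `hd_all`,
#'   `sd_all`.
#' @export
group_summary <- function(assignments, grouping, tree) {
  labels <- assignment_labels(assignments)
  nodes <- assignment_nodes(assignments)
  missing <- setdiff(names(labels), names(grouping))
  if (length(missing)) {
    stop("samples missing from grouping: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  crown <- bt_in_crown(tree, nodes)
  names(crown) <- names(nodes)
  one <- function(samples, group) {
    lab <- labels[samples]
    cr <- crown[samples]
    hd <- function(l) {
      if (length(l) < 2) return(c(NA_real_, NA_real_))
      d <- haplotype_diversity(table(l))
      c(d$Hd, d$SD)
    }
    h_cr <- hd(lab[cr])
    h_all <- hd(lab)
    data.frame(group = group, n = length(samples),
               n_crown = sum(cr), n_noncrown = sum(!cr),
               ht_total = length(unique(lab)),
               ht_crown = length(unique(lab[cr])),
               ht_noncrown = length(unique(lab[!cr])),
               hd_crown = h_cr[1], sd_crown = h_cr[2],
               hd_all = h_all[1], sd_all = h_all[2],
               stringsAsFactors = FALSE)
  }
  by_group <- split(names(labels), grouping[names(labels)])
  rows <- mapply(one, by_group, names(by_group), SIMPLIFY = FALSE)
  out <- do.call(rbind, c(rows, list(one(names(labels), "Total"))))
  rownames(out) <- NULL
  out
}

#' Crown membership and terminal-resolution percentages
#'
#' The headline partition of a cohort: percentage of samples falling in the
#' Crown haplogroup, and of those, the split between predefined terminal HTs
#' and inner-node `"*HT"` allocations. Percentages are rounded to the nearest
#' integer (reporting convention for these headline figures).
#'
#' @param assignments `ht_assignments` data.frame from [batch_call()].
#' @param tree the `backbone_tree` (must carry `crown_root`).
#' @return list of class `crown_fraction`: counts and integer percentages,
#'   plus the number of distinct Crown haplotype labels and of inner nodes
#'   carrying at least one sample.
#' @export
crown_fraction <- function(assignments, tree) {
  if (is.na(tree$crown_root)) stop("tree has no crown_root", call. = FALSE)
  labels <- assignment_labels(assignments)
  nodes <- assignment_nodes(assignments)
  crown <- bt_in_crown(tree, nodes)
  n <- length(nodes)
  n_crown <- sum(crown)
  df <- data.frame(label = labels[crown],
                   terminal = !grepl("\\*$", labels[crown]))
  n_term <- sum(df$terminal)
  structure(list(
    n = n, n_crown = n_crown,
    pct_crown = round(100 * n_crown / n),
    n_terminal = n_term, n_inner = n_crown - n_term,
    pct_terminal = round(100 * n_term / n_crown),
    pct_inner = round(100 * (n_crown - n_term) / n_crown),
    n_crown_ht = length(unique(df$label)),
    n_terminal_ht = length(unique(df$label[df$terminal])),
    n_inner_nodes_used = length(unique(df$label[!df$terminal]))
  ), class = "crown_fraction")
}

#' @export
print.crown_fraction <- function(x, ...) {
  cat(sprintf("Crown: %d/%d samples (%d%%)\n", x$n_crown, x$n, x$pct_crown))
  cat(sprintf("  terminal HTs: %d (%d%%); inner *HTs: %d (%d%%)\n",
              x$n_terminal, x$pct_terminal, x$n_inner, x$pct_inner))
  cat(sprintf("  %d distinct Crown labels (%d terminal, %d inner nodes used)\n",
              x$n_crown_ht, x$n_terminal_ht, x$n_inner_nodes_used))
  invisible(x)
}
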