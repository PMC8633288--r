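# Differential-expression machinery: FPKM, a pooled two-library proportion
# test, Benjamini-Hochberg adjustment, threshold filters, and the
# shared-repression set logic across mutants.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = 1e9 * count / (length * library_size)`.
#'
#' @param counts Numeric vector or genes-by-samples matrix of fragment
#'   counts.
#' @param gene_lengths Transcript lengths in bp (recycled along genes).
#' @param library_sizes Total mapped fragments per sample (recycled along
#'   samples for a matrix input).
#' @return Same shape as `counts`.
#' @export
#' @examples
#' fpkm(100, 1000, 1e7) # 10
fpkm <- function(counts, gene_lengths, library_sizes) {
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    abort("zero or negative gene length")
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    abort("library sizes must be positive")
  }
  if (is.matrix(counts)) {
    sweep(counts / gene_lengths, 2L, library_sizes, "/") * 1e9
  } else {
    1e9 * counts / (gene_lengths * library_sizes)
  }
}

#' Pooled two-proportion z-test between two sequencing libraries
#'
#' Tests whether a gene's fragment fraction differs between two libraries
#' under binomial sampling: with pooled fraction
#' `p = (k1 + k2) / (n1 + n2)`, the statistic is
#' `z = (k1/n1 - k2/n2) / sqrt(p (1 - p) (1/n1 + 1/n2))` and the p value is
#' two-sided normal. A degenerate pooled fraction (0 or 1) carries no
#' information and returns p = 1. All arguments are vectorized.
#'
#' @param k1,k2 Gene fragment counts in the two libraries.
#' @param n1,n2 Library totals (positive).
#' @return Two-sided p values.
#' @export
#' @examples
#' two_library_test(30, 1e6, 60, 1e6)
two_library_test <- function(k1, n1, k2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    abort("library totals must be positive")
  }
  if (any(k1 < 0) || any(k2 < 0) || any(k1 > n1) || any(k2 > n2)) {
    abort("counts must satisfy 0 <= k <= n")
  }
  p_hat <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  p <- 2 * pnorm(-abs(z))
  p[p_hat <= 0 | p_hat >= 1] <- 1
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`): sort ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j`, cap at 1, restore input order.
#'
#' @param p P values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

check_expression_inputs <- function(counts, samples) {
  check_columns(counts, c("gene", "length"), "counts table")
  check_columns(samples, c("sample", "group"), "samples table")
  missing <- setdiff(samples$sample, names(counts))
  if (length(missing) > 0L) {
    abort(sprintf("counts table lacks sample column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample)) {
    abort("every sample must be assigned to exactly one group")
  }
  if (!"library_size" %in% names(samples)) {
    samples$library_size <- vapply(samples$sample,
                                   function(s) sum(counts[[s]]), numeric(1L))
  }
  if (any(samples$library_size <= 0)) {
    abort("library sizes must be positive")
  }
  samples
}

#' Call differentially expressed genes for one comparison
#'
#' A gene is differentially expressed when all three conditions hold
#' strictly: the larger of the two group-mean FPKMs exceeds `fpkm_min`, the
#' fold change (group-mean FPKM of the case over the control) is above
#' `fc_up` or below `fc_down`, and the BH-adjusted p value of the pooled
#' two-library test (replicate counts summed per group) is below `q_max`.
#' Genes with both group means zero are skipped (direction `"ns"`, no test).
#'
#' @param counts Tibble with columns `gene`, `length`, and one count column
#'   per sample.
#' @param samples Tibble with columns `sample`, `group`, and optionally
#'   `library_size` (per-sample total mapped fragments; defaults to column
#'   sums).
#' @param case,control Group names to compare.
#' @param fpkm_min,fc_up,fc_down,q_max Strict thresholds
#'   (defaults 1, 1.5, 0.6666, 0.05).
#' @param pseudo_fpkm Pseudo-FPKM added to both group means before the fold
#'   change (default 0).
#' @return A tibble with one row per gene: `gene`, `comparison`,
#'   `mean_fpkm_case`, `mean_fpkm_control`, `fold_change`, `p_raw`, `p_adj`,
#'   `direction` (`"up"`, `"down"`, `"ns"`).
#' @export
call_degs <- function(counts, samples, case, control,
                      fpkm_min = 1, fc_up = 1.5, fc_down = 0.6666,
                      q_max = 0.05, pseudo_fpkm = 0) {
  samples <- check_expression_inputs(counts, samples)
  for (g in c(case, control)) {
    if (!g %in% samples$group) {
      abort(sprintf("group '%s' not present in the samples table", g))
    }
  }
  case_samples <- samples$sample[samples$group == case]
  ctrl_samples <- samples$sample[samples$group == control]

  count_mat <- as.matrix(counts[, samples$sample, drop = FALSE])
  lib <- samples$library_size[match(colnames(count_mat), samples$sample)]
  fpkm_mat <- fpkm(count_mat, counts$length, lib)
  mean_case <- rowMeans(fpkm_mat[, case_samples, drop = FALSE])
  mean_ctrl <- rowMeans(fpkm_mat[, ctrl_samples, drop = FALSE])

  k1 <- rowSums(count_mat[, case_samples, drop = FALSE])
  n1 <- sum(lib[colnames(count_mat) %in% case_samples])
  k2 <- rowSums(count_mat[, ctrl_samples, drop = FALSE])
  n2 <- sum(lib[colnames(count_mat) %in% ctrl_samples])

  tested <- mean_case > 0 | mean_ctrl > 0
  p_raw <- rep(NA_real_, nrow(counts))
  p_raw[tested] <- two_library_test(k1[tested], n1, k2[tested], n2)
  p_adj <- rep(NA_real_, nrow(counts))
  p_adj[tested] <- bh_adjust(p_raw[tested])

  fold_change <- rep(NA_real_, nrow(counts))
  fold_change[tested] <- (mean_case[tested] + pseudo_fpkm) /
    (mean_ctrl[tested] + pseudo_fpkm)

  expressed <- pmax(mean_case, mean_ctrl) > fpkm_min
  sig <- tested & expressed & !is.na(p_adj) & p_adj < q_max &
    is.finite(fold_change)
  direction <- rep("ns", nrow(counts))
  direction[sig & fold_change > fc_up] <- "up"
  direction[sig & fold_change < fc_down] <- "down"

  tibble(
    gene = counts$gene,
    comparison = paste(case, "vs", control),
    mean_fpkm_case = mean_case,
    mean_fpkm_control = mean_ctrl,
    fold_change = fold_change,
    p_raw = p_raw,
    p_adj = p_adj,
    direction = direction
  )
}

#' Run every mutant-versus-control comparison
#'
#' @inheritParams call_degs
#' @param control Control group; every other group becomes a case.
#' @return An object of class `"deg_result"` holding the stacked per-gene
#'   table (see [call_degs()]) plus the thresholds used; supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
deg_analysis <- function(counts, samples, control,
                         fpkm_min = 1, fc_up = 1.5, fc_down = 0.6666,
                         q_max = 0.05, pseudo_fpkm = 0) {
  samples <- check_expression_inputs(counts, samples)
  cases <- setdiff(unique(samples$group), control)
  if (length(cases) == 0L) {
    abort("no case group: every sample belongs to the control")
  }
  table <- dplyr::bind_rows(lapply(cases, function(g) {
    call_degs(counts, samples, case = g, control = control,
              fpkm_min = fpkm_min, fc_up = fc_up, fc_down = fc_down,
              q_max = q_max, pseudo_fpkm = pseudo_fpkm)
  }))
  structure(
    list(table = table, control = control, cases = cases,
         thresholds = list(fpkm_min = fpkm_min, fc_up = fc_up,
                           fc_down = fc_down, q_max = q_max)),
    class = "deg_result"
  )
}

#' @export
print.deg_result <- function(x, ...) {
  cat("<deg_result>\n")
  smry <- dplyr::count(x$table, .data$comparison, .data$direction)
  for (cmp in unique(smry$comparison)) {
    s <- smry[smry$comparison == cmp, ]
    n_up <- sum(s$n[s$direction == "up"])
    n_down <- sum(s$n[s$direction == "down"])
    cat(sprintf("  %s: %d up, %d down\n", cmp, n_up, n_down))
  }
  invisible(x)
}

#' Genes repressed in at least `min_k` comparisons
#'
#' The cross-mutant intersection step: collect per-comparison downregulated
#' gene sets and keep genes appearing in `min_k` or more of them
#' (`min_k = 1` is the union, `min_k` equal to the number of sets the
#' intersection).
#'
#' @param deg_sets A `"deg_result"` object, or a named list of character
#'   vectors of downregulated genes (one per comparison).
#' @param min_k Minimum number of comparisons a gene must appear in.
#' @return Sorted character vector of gene ids.
#' @export
shared_down <- function(deg_sets, min_k = 2) {
  if (inherits(deg_sets, "deg_result")) {
    tab <- deg_sets$table
    deg_sets <- lapply(
      split(tab, tab$comparison),
      function(d) d$gene[d$direction == "down"]
    )
  }
  if (!is.list(deg_sets) || length(deg_sets) < 2L) {
    abort("shared_down needs at least two comparisons")
  }
  check_number(min_k, "min_k", min = 1, integerish = TRUE)
  counts <- table(unlist(lapply(deg_sets, unique)))
  sort(names(counts)[counts >= min_k])
}

#' Simulate a replicated two-group expression matrix with seeded DEGs
#'
#' Poisson fragment counts around per-gene expected fractions (log-normal
#' across genes, proportional to transcript length), with a chosen subset of
#' genes repressed by a constant fold in the case group. The binomial-family
#' noise matches the sampling model the two-library test assumes, so seeded
#' effects are recoverable and null genes are calibrated.
#'
#' @param n_genes Number of genes.
#' @param n_down Number of seeded repressed genes (the first `n_down` ids).
#' @param fold Repression fold (case mean = control mean / `fold`).
#' @param groups Character vector of two group names (control first).
#' @param reps Biological replicates per group.
#' @param lib_size Expected fragments per library.
#' @param seed Seed.
#' @return A list: `counts` and `samples` tibbles (ready for [call_degs()])
#'   and `down_genes`, the seeded ids.
#' @export
simulate_expression <- function(n_genes = 1000, n_down = 50, fold = 5,
                                groups = c("control", "mutant"), reps = 3,
                                lib_size = 2e6, seed = 1) {
  stopifnot(length(groups) == 2L)
  with_seed(seed, {
    gene <- sprintf("gene%04d", seq_len(n_genes))
    len <- sample(500:5000, n_genes, replace = TRUE)
    expr <- stats::rlnorm(n_genes, meanlog = 1, sdlog = 1)
    weight_ctrl <- expr * len
    weight_case <- weight_ctrl
    down <- seq_len(n_down)
    weight_case[down] <- weight_case[down] / fold

    # both groups share the control normalisation so genes outside the
    # seeded set keep identical expected fractions — repressing one gene
    # must not shift every other gene's proportion (the null would be
    # compositionally biased otherwise)
    frac_ctrl <- weight_ctrl / sum(weight_ctrl)
    frac_case <- weight_case / sum(weight_ctrl)
    sample_names <- c(paste0(groups[1L], "_", seq_len(reps)),
                      paste0(groups[2L], "_", seq_len(reps)))
    mat <- cbind(
      matrix(rpois(n_genes * reps, lib_size * frac_ctrl), n_genes, reps),
      matrix(rpois(n_genes * reps, lib_size * frac_case), n_genes, reps)
    )
    colnames(mat) <- sample_names
    counts <- dplyr::bind_cols(tibble(gene = gene, length = len),
                               as_tibble(mat))
    samples <- tibble(
      sample = sample_names,
      group = rep(groups, each = reps),
      library_size = rep(lib_size, 2L * reps)
    )
    list(counts = counts, samples = samples, down_genes = gene[down])
  })
}
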