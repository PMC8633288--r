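# Interval narrowing from recombinant marker genotypes and progeny tests.
# Genotypes are coded in allele space: A = low-branching parent (ST147/CC
# like), B = high-branching parent (ST024/MM like); AB is the heterozygote
# (rendered "CM" in breeding shorthand).

#' Validate a marker map
#'
#' @param markers Tibble with columns `marker`, `chrom`, `pos` (1-based
#'   physical positions, strictly increasing, at least two markers on one
#'   chromosome).
#' @return The validated tibble.
#' @export
marker_map <- function(markers) {
  check_columns(markers, c("marker", "chrom", "pos"), "marker map")
  if (length(unique(markers$chrom)) != 1L) {
    abort("marker map must describe a single chromosome")
  }
  if (nrow(markers) < 2L) {
    abort("marker map needs at least two markers")
  }
  if (is.unsorted(markers$pos, strictly = TRUE)) {
    abort("marker positions must be strictly increasing")
  }
  if (anyDuplicated(markers$marker)) {
    abort("marker names must be unique")
  }
  as_tibble(markers)
}

validate_line <- function(genotypes, line_id) {
  ok <- c("AA", "AB", "BB")
  if (any(!genotypes %in% ok)) {
    abort(sprintf("line %s: genotype calls must be AA, AB, or BB", line_id))
  }
  if (length(unique(genotypes)) == 1L) {
    abort(sprintf("line %s is not a recombinant: constant genotype across all markers",
                  line_id))
  }
  invisible(genotypes)
}

# genotype class implied by a progeny test under the single-QTL model
target_genotypes <- function(progeny_test, model) {
  switch(progeny_test,
    segregating = "AB",
    uniform_high = if (model == "dominant_high") c("BB", "AB") else "BB",
    uniform_low = "AA",
    abort(sprintf("unknown progeny test class '%s'", progeny_test))
  )
}

#' Interval constraint implied by one recombinant line
#'
#' Under a single-QTL model, a segregating progeny test places the QTL inside
#' the line's heterozygous segment(s); a uniform test places it inside the
#' homozygous segment matching the phenotype class. Breakpoints are only
#' localized to the inter-marker gap where the genotype changes, so every
#' segment is extended to the nearest genotyped marker on each side (open at
#' the markers) and to infinity past the outermost markers.
#'
#' @param genotypes Character vector of genotype calls (`"AA"`, `"AB"`,
#'   `"BB"`), one per marker in map order.
#' @param progeny_test One of `"segregating"`, `"uniform_high"`,
#'   `"uniform_low"`.
#' @param markers A [marker_map()].
#' @param model `"partial"` (default; heterozygous progeny are
#'   distinguishable, so `uniform_high` implies a BB segment) or
#'   `"dominant_high"` (`uniform_high` also compatible with AB segments).
#' @param line_id Identifier used in error messages.
#' @return A two-column matrix of open intervals (bp) compatible with the
#'   observation.
#' @export
line_constraint <- function(genotypes, progeny_test, markers,
                            model = c("partial", "dominant_high"),
                            line_id = "?") {
  model <- match.arg(model)
  markers <- marker_map(markers)
  if (length(genotypes) != nrow(markers)) {
    abort(sprintf("line %s: %d genotype calls for %d markers",
                  line_id, length(genotypes), nrow(markers)))
  }
  validate_line(genotypes, line_id)
  if (progeny_test == "untested") {
    abort(sprintf("line %s is untested and carries no constraint", line_id))
  }
  target <- target_genotypes(progeny_test, model)

  pos <- markers$pos
  m <- length(pos)
  in_target <- genotypes %in% target
  if (!any(in_target)) {
    abort(sprintf(
      "inconsistency: line %s (%s) has no %s segment compatible with its progeny test",
      line_id, progeny_test, paste(target, collapse = "/")))
  }
  r <- rle(in_target)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  segs <- lapply(which(r$values), function(k) {
    i <- starts[k]
    j <- stops[k]
    lo <- if (i == 1L) -Inf else pos[i - 1L]
    hi <- if (j == m) Inf else pos[j + 1L]
    c(lo, hi)
  })
  do.call(rbind, segs)
}

#' Narrow the QTL interval from a panel of recombinant lines
#'
#' Intersects the interval constraints of every informative line (progeny
#' test not `"untested"`) and reports the tightest flanking-marker pair
#' around the surviving region. An empty intersection raises an
#' inconsistency error naming the line at which it emptied.
#'
#' @param lines Long tibble with columns `line`, `marker`, `genotype`,
#'   `progeny_test` (constant within a line).
#' @param markers A [marker_map()].
#' @param model See [line_constraint()].
#' @return An object of class `"fine_map"` with the interval, flanking
#'   markers, and per-line constraints; see also [tidy()] and [glance()].
#' @export
narrow_interval <- function(lines, markers, model = c("partial", "dominant_high")) {
  model <- match.arg(model)
  markers <- marker_map(markers)
  check_columns(lines, c("line", "marker", "genotype", "progeny_test"), "lines")
  if (!all(lines$marker %in% markers$marker)) {
    abort("lines mention markers absent from the marker map")
  }

  ids <- unique(lines$line)
  constraints <- list()
  for (id in ids) {
    li <- lines[lines$line == id, ]
    pt <- unique(li$progeny_test)
    if (length(pt) != 1L) {
      abort(sprintf("line %s has conflicting progeny_test labels", id))
    }
    if (pt == "untested") next
    geno <- li$genotype[match(markers$marker, li$marker)]
    if (anyNA(geno)) {
      abort(sprintf("line %s lacks calls at some markers", id))
    }
    constraints[[as.character(id)]] <-
      line_constraint(geno, pt, markers, model = model, line_id = id)
  }
  if (length(constraints) == 0L) {
    abort("no informative line: every progeny test is 'untested'")
  }

  current <- matrix(c(-Inf, Inf), ncol = 2L)
  for (id in names(constraints)) {
    current <- intervals_intersect(current, constraints[[id]])
    if (nrow(current) == 0L) {
      abort(sprintf(
        "inconsistency: constraints became contradictory when adding line %s", id))
    }
  }

  lo <- min(current[, 1L])
  hi <- max(current[, 2L])
  pos <- markers$pos
  left_i <- if (any(pos <= lo)) max(which(pos <= lo)) else NA_integer_
  right_i <- if (any(pos >= hi)) min(which(pos >= hi)) else NA_integer_

  structure(
    list(
      interval = c(lo = lo, hi = hi),
      left_marker = if (is.na(left_i)) NA_character_ else markers$marker[left_i],
      right_marker = if (is.na(right_i)) NA_character_ else markers$marker[right_i],
      chrom = markers$chrom[1L],
      markers = markers,
      constraints = constraints,
      model = model,
      n_lines = length(constraints)
    ),
    class = "fine_map"
  )
}

#' @export
print.fine_map <- function(x, ...) {
  cat("<fine_map>\n")
  wid <- x$interval["hi"] - x$interval["lo"]
  cat(sprintf("  QTL interval on %s: (%s, %s) = (%s, %s) bp%s, from %d informative line(s)\n",
              x$chrom,
              x$left_marker %||% NA, x$right_marker %||% NA,
              format(x$interval["lo"], big.mark = ","),
              format(x$interval["hi"], big.mark = ","),
              if (is.finite(wid)) sprintf(", width %.2f kb", wid / 1e3) else "",
              x$n_lines))
  invisible(x)
}

#' Simulate a recombinant fine-mapping panel with known truth
#'
#' Draws F2 plants over the marker grid (same Haldane gamete model as
#' [simulate_f2_population()]), keeps those recombinant across the markers,
#' and labels each with the progeny test its true QTL genotype would give
#' (AB segregating, BB uniform high, AA uniform low).
#'
#' @param markers A [marker_map()].
#' @param qtl_pos_bp True QTL position (inside the marker span for a bounded
#'   interval).
#' @param n_lines Number of recombinant lines to collect.
#' @param cm_per_mb Genetic map scale.
#' @param seed Seed.
#' @return A list: `lines` (long tibble ready for [narrow_interval()]) and
#'   `qtl_pos_bp`.
#' @export
simulate_recombinant_panel <- function(markers, qtl_pos_bp, n_lines = 38,
                                       cm_per_mb = 1.5, seed = 1) {
  markers <- marker_map(markers)
  check_number(qtl_pos_bp, "qtl_pos_bp", min = 1)
  with_seed(seed, {
    pos_all <- sort(c(markers$pos, qtl_pos_bp))
    qtl_idx <- match(qtl_pos_bp, pos_all)
    gpos <- pos_all / 1e6 * cm_per_mb
    span_cm <- max(gpos) - min(gpos)
    # simulate over a map slightly wider than the marker span so breakpoints
    # can fall beyond the outermost markers too
    map_len <- span_cm + 2
    gpos <- gpos - min(gpos) + 1

    out <- vector("list", n_lines)
    collected <- 0L
    attempts <- 0L
    while (collected < n_lines && attempts < 10000L * n_lines) {
      attempts <- attempts + 1L
      dose <- sample_gamete(gpos, map_len) + sample_gamete(gpos, map_len)
      marker_dose <- dose[-qtl_idx]
      if (length(unique(marker_dose)) == 1L) next
      collected <- collected + 1L
      qtl_geno <- c("AA", "AB", "BB")[dose[qtl_idx] + 1L]
      out[[collected]] <- tibble(
        line = sprintf("R%03d", collected),
        marker = markers$marker,
        genotype = c("AA", "AB", "BB")[marker_dose + 1L],
        progeny_test = switch(qtl_geno,
                              AA = "uniform_low",
                              AB = "segregating",
                              BB = "uniform_high")
      )
    }
    if (collected < n_lines) {
      abort("failed to collect enough recombinants; widen the marker span or raise cm_per_mb")
    }
    list(lines = dplyr::bind_rows(out), qtl_pos_bp = qtl_pos_bp)
  })
}
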