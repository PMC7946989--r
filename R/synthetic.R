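# Synthetic multi-cohort expression data with the statistical structure the
# downstream rule learning assumes: case/control classes, graded case
# subtypes, planted gene pairs co-regulated in cases only, per-gene mean
# shifts, Gaussian noise and additive per-cohort offsets.

#' Specify a synthetic multi-cohort expression study
#'
#' Describes the generative model for [generate_cohorts()]: every gene is
#' Gaussian noise around zero on a log-like scale; selected genes receive
#' per-subtype mean shifts; selected gene pairs are drawn from a bivariate
#' normal whose correlation differs between cases and controls; each cohort
#' adds an independent per-gene offset (batch effect).
#'
#' The first element of `subtype_labels` is the control group. Subtype
#' severity scores must be non-decreasing along `subtype_labels`; when
#' `scale_rho_by_severity` is `TRUE` (default) the planted case correlation
#' of a sample is `rho_case * severity/max(severity)`, so milder subtypes
#' carry proportionally weaker co-regulation.
#'
#' @param n_cohorts number of cohorts to generate.
#' @param n_genes number of genes per cohort.
#' @param samples_per_subgroup named integer vector, subgroup label ->
#'   samples per cohort; names must equal `subtype_labels`.
#' @param subtype_labels ordered character vector; first label is control.
#' @param severity named numeric vector of severity scores per subtype,
#'   non-decreasing along `subtype_labels`.
#' @param planted_pairs data frame with columns `gene_i`, `gene_j` (1-based
#'   gene indices), `rho_case`, `rho_control` (each in (-1, 1)).
#' @param shift_genes named list: gene index (as character) -> named numeric
#'   vector of per-subtype mean shifts, in expression units (defaults are in
#'   multiples of `noise_sd`).
#' @param noise_sd positive residual standard deviation.
#' @param cohort_offset_sd non-negative sd of the per-cohort per-gene offset.
#' @param scale_rho_by_severity scale each pair's `rho_case` by relative
#'   subtype severity.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cohorts = 1L,
                           n_genes = 12L,
                           samples_per_subgroup = c(control = 50L, autism = 50L),
                           subtype_labels = names(samples_per_subgroup),
                           severity = NULL,
                           planted_pairs = NULL,
                           shift_genes = list(),
                           noise_sd = 1,
                           cohort_offset_sd = 0,
                           scale_rho_by_severity = TRUE,
                           seed = 1L) {
  assert_positive_int(n_cohorts, "n_cohorts")
  assert_positive_int(n_genes, "n_genes")
  # tolerate JSON-config shapes: named lists for named vectors
  if (is.list(samples_per_subgroup))
    samples_per_subgroup <- unlist(samples_per_subgroup)
  if (is.list(severity)) severity <- unlist(severity)
  if (length(shift_genes)) shift_genes <- lapply(shift_genes, unlist)
  if (missing(subtype_labels) || is.null(subtype_labels))
    subtype_labels <- names(samples_per_subgroup)
  if (is.null(names(samples_per_subgroup)))
    stop("`samples_per_subgroup` must be named by subgroup label")
  if (any(samples_per_subgroup < 1))
    stop("all subgroup counts must be > 0; empty subgroup rejected")
  subtype_labels <- as.character(subtype_labels)
  if (!setequal(subtype_labels, names(samples_per_subgroup)))
    stop("`subtype_labels` must match the names of `samples_per_subgroup`")
  if (is.null(severity))
    severity <- setNames(seq_along(subtype_labels) - 1, subtype_labels)
  if (!all(subtype_labels %in% names(severity)))
    stop("`severity` must name every subtype")
  sev <- severity[subtype_labels]
  if (any(diff(sev) < 0))
    stop("severity scores must be monotone (non-decreasing) over the subtype order")
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    need <- c("gene_i", "gene_j", "rho_case", "rho_control")
    if (!all(need %in% names(planted_pairs)))
      stop("`planted_pairs` needs columns gene_i, gene_j, rho_case, rho_control")
    if (any(planted_pairs$gene_i > n_genes | planted_pairs$gene_j > n_genes |
            planted_pairs$gene_i < 1 | planted_pairs$gene_j < 1))
      stop("planted gene index out of range [1, n_genes]")
    if (any(abs(planted_pairs$rho_case) >= 1 | abs(planted_pairs$rho_control) >= 1))
      stop("|rho| must be < 1 for every planted pair")
  }
  if (length(shift_genes)) {
    idx <- as.integer(names(shift_genes))
    if (any(is.na(idx)) || any(idx < 1 | idx > n_genes))
      stop("`shift_genes` names must be gene indices in [1, n_genes]")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (cohort_offset_sd < 0) stop("`cohort_offset_sd` must be >= 0")
  structure(list(
    n_cohorts = as.integer(n_cohorts), n_genes = as.integer(n_genes),
    samples_per_subgroup = samples_per_subgroup[subtype_labels],
    subtype_labels = subtype_labels, severity = sev,
    control_label = subtype_labels[1L],
    planted_pairs = planted_pairs, shift_genes = shift_genes,
    noise_sd = noise_sd, cohort_offset_sd = cohort_offset_sd,
    scale_rho_by_severity = isTRUE(scale_rho_by_severity),
    seed = as.integer(seed)), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:", x$n_cohorts, "cohort(s),", x$n_genes, "genes,",
      sum(x$samples_per_subgroup), "samples/cohort\n")
  cat("  subgroups:", paste(sprintf("%s=%d", names(x$samples_per_subgroup),
                                    x$samples_per_subgroup), collapse = ", "), "\n")
  cat("  planted pairs:", if (is.null(x$planted_pairs)) 0 else nrow(x$planted_pairs),
      "| shifted genes:", length(x$shift_genes), "\n")
  invisible(x)
}

#' Generate synthetic expression cohorts
#'
#' Draws one expression matrix per cohort under the model described by a
#' [synthetic_spec()]. All genes start as independent `N(0, noise_sd)` noise
#' plus a per-cohort per-gene `N(0, cohort_offset_sd)` offset; planted pairs
#' are redrawn from a bivariate normal with the class-specific correlation;
#' per-subtype mean shifts are added last. Sample ids are namespaced by
#' cohort so they stay globally unique after merging.
#'
#' @param spec a [synthetic_spec()].
#' @return list of `expression_matrix` objects (one per cohort), each with
#'   `values` (samples x genes), `sample_meta` (sample_id, cohort_id, class,
#'   subtype, sex, age) and `gene_ids`.
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  max_sev <- max(spec$severity)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_cohorts), function(ci) {
      counts <- spec$samples_per_subgroup
      subtype <- rep(names(counts), counts)
      n <- length(subtype)
      cohort_id <- sprintf("c%d", ci)
      meta <- data.frame(
        sample_id = sprintf("%s_s%03d", cohort_id, seq_len(n)),
        cohort_id = cohort_id,
        class = ifelse(subtype == spec$control_label, "control", "case"),
        subtype = subtype,
        sex = sample(c("M", "F"), n, replace = TRUE),
        age = pmax(2, round(rnorm(n, 8, 3))),
        stringsAsFactors = FALSE)
      vals <- matrix(rnorm(n * spec$n_genes, 0, spec$noise_sd), n, spec$n_genes,
                     dimnames = list(meta$sample_id, gene_ids))
      offset <- rnorm(spec$n_genes, 0, spec$cohort_offset_sd)
      vals <- sweep(vals, 2L, offset, "+")
      if (!is.null(spec$planted_pairs)) {
        for (p in seq_len(nrow(spec$planted_pairs))) {
          pp <- spec$planted_pairs[p, ]
          for (g in names(counts)) {
            rows <- which(subtype == g)
            rho <- if (g == spec$control_label) pp$rho_control
                   else if (spec$scale_rho_by_severity && max_sev > 0)
                     pp$rho_case * spec$severity[[g]] / max_sev
                   else pp$rho_case
            z1 <- rnorm(length(rows)); z2 <- rnorm(length(rows))
            vals[rows, pp$gene_i] <- offset[pp$gene_i] + spec$noise_sd * z1
            vals[rows, pp$gene_j] <- offset[pp$gene_j] +
              spec$noise_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
          }
        }
      }
      for (g in names(spec$shift_genes)) {
        sh <- spec$shift_genes[[g]]
        for (st in names(sh)) {
          rows <- which(subtype == st)
          vals[rows, as.integer(g)] <- vals[rows, as.integer(g)] + sh[[st]]
        }
      }
      structure(list(values = vals, sample_meta = meta, gene_ids = gene_ids),
                class = "expression_matrix")
    })
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "genes; cohort", unique(x$sample_meta$cohort_id), "\n")
  invisible(x)
}

#' Generate a synthetic functional-term database
#'
#' Stand-in for curated term-to-gene annotations: `n_terms` gene sets each
#' sampled without replacement from `gene_ids`.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_terms number of terms (0 allowed).
#' @param genes_per_term genes per term; must be <= `length(gene_ids)`.
#' @param seed integer RNG seed.
#' @return named list term id -> character vector of member genes.
#' @export
generate_term_db <- function(gene_ids, n_terms, genes_per_term, seed = 1L) {
  if (n_terms < 0 || n_terms != floor(n_terms)) stop("`n_terms` must be >= 0")
  if (genes_per_term > length(gene_ids))
    stop("`genes_per_term` exceeds the number of genes")
  if (n_terms == 0) return(setNames(list(), character(0)))
  with_seed(seed, {
    terms <- lapply(seq_len(n_terms), function(i)
      sort(sample(gene_ids, genes_per_term, replace = FALSE)))
    names(terms) <- sprintf("term%03d", seq_len(n_terms))
    terms
  })
}

#' Write an expression matrix and its metadata as TSV
#'
#' `<prefix>_expression.tsv` holds samples as rows (first column
#' `sample_id`, remaining columns genes); `<prefix>_meta.tsv` holds the
#' sample metadata.
#'
#' @param x an `expression_matrix`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths written.
#' @export
write_expression_matrix <- function(x, prefix) {
  stopifnot(inherits(x, "expression_matrix"))
  expr_path <- paste0(prefix, "_expression.tsv")
  meta_path <- paste0(prefix, "_meta.tsv")
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(expr_path, meta_path))
}

#' Read an expression matrix written by [write_expression_matrix()]
#' @param expr_path expression TSV (first column `sample_id`).
#' @param meta_path metadata TSV with matching `sample_id` column.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(expr_path, meta_path) {
  df <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$sample_id
  meta <- meta[match(df$sample_id, meta$sample_id), , drop = FALSE]
  structure(list(values = vals, sample_meta = meta, gene_ids = colnames(vals)),
            class = "expression_matrix")
}

#' Write a term database as a two-column TSV (term_id, gene_id)
#' @param terms named list as returned by [generate_term_db()].
#' @param path output file.
#' @export
write_term_db <- function(terms, path) {
  df <- data.frame(term_id = rep(names(terms), lengths(terms)),
                   gene_id = unlist(terms, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stated synthetic worlds used by the validation suite
#'
#' `spec_planted_pair()` describes a single case-control cohort (100 + 100
#' samples, 10 genes) with one strongly co-regulated gene pair in cases
#' (`rho_case = 0.9`, `rho_control = 0`) and strong (+2 noise-sd) case
#' shifts on the paired genes — the world in which the method should
#' recover the planted pair as the strongest co-predictive edge.
#'
#' `spec_severity_gradient()` mirrors a three-cohort case-control study
#' with three case subtypes of graded severity (control, AS, PDD-NOS,
#' autism; severities 0-3): each cohort has 60 controls and 30 samples per
#' subtype, six genes shifted by 0.6 noise-sd per severity unit, and one
#' planted pair whose case correlation scales with severity. Distances
#' from the control subnetwork should recover the planted ordering
#' autism > PDD-NOS > AS.
#'
#' @param seed integer RNG seed for the generated world.
#' @return a [synthetic_spec()].
#' @export
spec_planted_pair <- function(seed = 1L) {
  synthetic_spec(
    n_cohorts = 1L, n_genes = 10L,
    samples_per_subgroup = c(control = 100L, autism = 100L),
    planted_pairs = data.frame(gene_i = 1, gene_j = 2,
                               rho_case = 0.9, rho_control = 0),
    shift_genes = list(`1` = c(autism = 2), `2` = c(autism = 2)),
    seed = seed)
}

#' @rdname spec_planted_pair
#' @export
spec_severity_gradient <- function(seed = 1L) {
  synthetic_spec(
    n_cohorts = 3L, n_genes = 12L,
    samples_per_subgroup = c(control = 60L, AS = 30L,
                             `PDD-NOS` = 30L, autism = 30L),
    severity = c(control = 0, AS = 1, `PDD-NOS` = 2, autism = 3),
    planted_pairs = data.frame(gene_i = 1, gene_j = 2,
                               rho_case = 0.9, rho_control = 0),
    shift_genes = setNames(lapply(1:6, function(g)
      c(AS = 0.6, `PDD-NOS` = 1.2, autism = 1.8)), as.character(1:6)),
    scale_rho_by_severity = TRUE, seed = seed)
}
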