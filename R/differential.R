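#' The seven study contrasts
#'
#' Pairwise comparisons relevant to the study design: each SALS subtype
#' against control within each tissue (four disease-state contrasts), and
#' motor cortex against spinal cord within each state (three tissue
#' contrasts).
#'
#' @return data.frame with columns `contrast_id`, `tissue_a`, `state_a`,
#'   `tissue_b`, `state_b`, `type` (`"state"` or `"tissue"`).
#' @export
study_contrasts <- function() {
  data.frame(
    contrast_id = c("cortex_SALS1_vs_cortex_CTRL",
                    "cortex_SALS2_vs_cortex_CTRL",
                    "spinal_SALS1_vs_spinal_CTRL",
                    "spinal_SALS2_vs_spinal_CTRL",
                    "cortex_SALS1_vs_spinal_SALS1",
                    "cortex_SALS2_vs_spinal_SALS2",
                    "cortex_CTRL_vs_spinal_CTRL"),
    tissue_a = c(rep("motor_cortex", 2), rep("spinal_cord", 2),
                 rep("motor_cortex", 3)),
    state_a = c("SALS1", "SALS2", "SALS1", "SALS2", "SALS1", "SALS2", "CTRL"),
    tissue_b = c(rep("motor_cortex", 2), rep("spinal_cord", 2),
                 rep("spinal_cord", 3)),
    state_b = c("CTRL", "CTRL", "CTRL", "CTRL", "SALS1", "SALS2", "CTRL"),
    type = c(rep("state", 4), rep("tissue", 3)),
    stringsAsFactors = FALSE
  )
}

#' Per-gene two-way ANOVA with FDR control
#'
#' Fits `expression ~ tissue * state` for every gene and reports F
#' statistics and p-values for the two main effects and their
#' interaction. Unbalanced designs are handled with marginal (Type-III,
#' sum-to-zero contrasts) sums of squares via [car::Anova()]; sequential
#' Type-I sums of squares are available by flag (the two agree exactly on
#' balanced designs). Benjamini-Hochberg adjusted values are computed per
#' effect across genes.
#'
#' Genes with zero residual variance are flagged `degenerate` and given
#' limiting values (F = 0, p = 1 when the effect carries no variation;
#' F = Inf, p = 0 when it does) instead of raising an error.
#'
#' @param matrix gene-level normalized [expr_matrix()].
#' @param metadata sample metadata (see [validate_metadata()]).
#' @param ss_type `"III"` (default) or `"I"`.
#' @return data.frame with one row per gene: F, p and BH-adjusted q for
#'   `tissue`, `state` and `interaction`, residual df, and a
#'   `degenerate` flag.
#' @export
two_way_anova <- function(matrix, metadata, ss_type = c("III", "I")) {
  ss_type <- match.arg(ss_type)
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$level != "gene") {
    stop("`two_way_anova()` expects a gene-level matrix", call. = FALSE)
  }
  meta <- validate_metadata(metadata, colnames(matrix$values))
  cell_counts <- table(meta$tissue, meta$state)
  if (any(cell_counts == 0)) {
    stop("empty factorial cell(s): ",
         paste(which(cell_counts == 0), collapse = ", "), call. = FALSE)
  }
  n <- nrow(meta)
  df_model <- data.frame(y = numeric(n), tissue = meta$tissue, state = meta$state)
  ctr <- list(tissue = "contr.sum", state = "contr.sum")

  effects <- c("tissue", "state", "tissue:state")
  genes <- rownames(matrix$values)
  out <- matrix(NA_real_, length(genes), 7,
                dimnames = list(genes, c("F_tissue", "F_state", "F_interaction",
                                         "p_tissue", "p_state", "p_interaction",
                                         "residual_df")))
  degenerate <- logical(length(genes))
  tol <- 1e-10

  for (g in seq_along(genes)) {
    df_model$y <- matrix$values[g, ]
    fit <- stats::lm(y ~ tissue * state, data = df_model, contrasts = ctr)
    rss <- sum(stats::residuals(fit)^2)
    total <- sum((df_model$y - mean(df_model$y))^2)
    if (rss <= tol * max(1, total)) {
      # zero residual variance: limiting values with a flag, never an error
      # (Type-I SS suffice here: the model is exact, so an effect either
      # carries variation or it does not)
      tab <- suppressWarnings(stats::anova(fit))
      ss <- tab[effects, "Sum Sq"]
      degenerate[g] <- TRUE
      Fv <- ifelse(ss <= tol * max(1, total), 0, Inf)
      pv <- ifelse(is.infinite(Fv), 0, 1)
      out[g, ] <- c(Fv, pv, tab["Residuals", "Df"])
      next
    }
    tab <- if (ss_type == "III") {
      car::Anova(fit, type = 3)
    } else {
      stats::anova(fit)
    }
    ss <- tab[effects, "Sum Sq"]
    dfs <- tab[effects, "Df"]
    ss_e <- tab["Residuals", "Sum Sq"]
    df_e <- tab["Residuals", "Df"]
    Fv <- (ss / dfs) / (ss_e / df_e)
    pv <- stats::pf(Fv, dfs, df_e, lower.tail = FALSE)
    out[g, ] <- c(Fv, pv, df_e)
  }

  res <- data.frame(gene_id = genes, out, degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$q_tissue <- benjamini_hochberg(res$p_tissue)
  res$q_state <- benjamini_hochberg(res$p_state)
  res$q_interaction <- benjamini_hochberg(res$p_interaction)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values, clipped at 1 and order-preserving with the
#' input (a validating wrapper around [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene log2 fold changes for a set of contrasts
#'
#' For each contrast, the log2 fold change is the difference of group
#' means on the log2 (normalized) scale: `mean(A) - mean(B)`. The linear
#' fold-change magnitude is `2^|log2_fc|`.
#'
#' @param matrix gene-level normalized [expr_matrix()].
#' @param metadata sample metadata.
#' @param contrasts contrast table as from [study_contrasts()].
#' @return data.frame with one row per gene x contrast: `gene_id`,
#'   `contrast_id`, `type`, `log2_fc`, `direction` (`up` iff log2_fc > 0),
#'   `fc` (linear magnitude).
#' @export
pairwise_fold_changes <- function(matrix, metadata, contrasts = study_contrasts()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$level != "gene") {
    stop("`pairwise_fold_changes()` expects a gene-level matrix", call. = FALSE)
  }
  meta <- validate_metadata(metadata, colnames(matrix$values))
  v <- matrix$values
  group_cols <- function(tissue, state) {
    cols <- which(meta$tissue == tissue & meta$state == state)
    if (length(cols) == 0) {
      stop("unknown or empty contrast group: ", tissue, "/", state,
           call. = FALSE)
    }
    cols
  }
  recs <- lapply(seq_len(nrow(contrasts)), function(i) {
    cc <- contrasts[i, ]
    a <- rowMeans(v[, group_cols(cc$tissue_a, cc$state_a), drop = FALSE])
    b <- rowMeans(v[, group_cols(cc$tissue_b, cc$state_b), drop = FALSE])
    lfc <- a - b
    data.frame(gene_id = rownames(v), contrast_id = cc$contrast_id,
               type = cc$type, log2_fc = lfc,
               direction = ifelse(lfc > 0, "up", "down"),
               fc = 2^abs(lfc), row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Select differentially expressed genes per contrast
#'
#' A gene is a DEG for a contrast when its relevant BH-adjusted ANOVA
#' p-value is below `alpha` (strict) and its linear fold-change magnitude
#' exceeds `fc_cut` (strict). Under the default `gating = "effect"`, a
#' disease-state contrast is gated on `q_state` or `q_interaction`, and a
#' tissue contrast on `q_tissue` or `q_interaction`; `gating = "any"`
#' accepts any of the three effects.
#'
#' @param anova output of [two_way_anova()].
#' @param pairwise output of [pairwise_fold_changes()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param fc_cut linear fold-change threshold (default 2).
#' @param gating `"effect"` (default) or `"any"`.
#' @return list with `records` (the pairwise table plus `passes_threshold`)
#'   and `degs` (named list: contrast id -> character vector of DEGs).
#' @export
select_degs <- function(anova, pairwise, alpha = 0.05, fc_cut = 2.0,
                        gating = c("effect", "any")) {
  gating <- match.arg(gating)
  if (!all(pairwise$gene_id %in% anova$gene_id)) {
    stop("pairwise records contain genes absent from the ANOVA table",
         call. = FALSE)
  }
  idx <- match(pairwise$gene_id, anova$gene_id)
  q_any <- with(anova, pmin(q_tissue, q_state, q_interaction))[idx]
  q_state_gate <- with(anova, pmin(q_state, q_interaction))[idx]
  q_tissue_gate <- with(anova, pmin(q_tissue, q_interaction))[idx]
  q_rel <- if (gating == "any") {
    q_any
  } else {
    ifelse(pairwise$type == "state", q_state_gate, q_tissue_gate)
  }
  pairwise$passes_threshold <- q_rel < alpha & pairwise$fc > fc_cut
  degs <- split(pairwise$gene_id[pairwise$passes_threshold],
                factor(pairwise$contrast_id[pairwise$passes_threshold],
                       levels = unique(pairwise$contrast_id)))
  list(records = pairwise, degs = lapply(degs, as.character))
}

#' Partition named sets into disjoint Venn regions
#'
#' @param sets named list (>= 2) of character vectors; names unique.
#' @return object of class `venn_partition`: `regions` data.frame with
#'   columns `region` (set names joined by `&`), `count`; `members` named
#'   list of the region memberships.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("sets must carry unique non-empty names", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  sig <- vapply(universe, function(el) {
    paste(nm[vapply(sets, function(s) el %in% s, logical(1))], collapse = "&")
  }, character(1))
  members <- split(universe, sig)
  regions <- data.frame(region = names(members),
                        count = vapply(members, length, integer(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(set_names = nm, regions = regions, members = members),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> sets:", paste(x$set_names, collapse = ", "), "\n")
  print(x$regions)
  invisible(x)
}
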