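#' Build design matrices for the hierarchical models
#'
#' Treatment-coded fixed-effect matrix from a model formula, plus a
#' per-participant random-effect matrix. Factors use the stated
#' reference levels (condition: sham; block: first post-baseline
#' block; fatigue: low). Baseline (block 1) measurements enter as a
#' covariate, so model rows are the post-baseline blocks. Every factor
#' cell implied by the fixed formula must be populated; missing cells
#' raise an error listing the absent combinations.
#'
#' @param table data frame with the outcome, covariates and a
#'   `participant` column
#' @param fixed one-sided formula for the fixed effects,
#'   e.g. `~ baseline + condition * block`
#' @param ranef one-sided formula for the per-participant random
#'   effects, e.g. `~ 1 + condition` (must use terms present in the
#'   fixed part)
#' @param outcome name of the outcome column
#' @return list with `y`, `X`, `Z`, `group`, `terms`
#' @export
build_design <- function(table, fixed, ranef = ~ 1,
                         outcome = "y") {
  stopifnot(outcome %in% names(table), "participant" %in% names(table))
  table <- droplevels(table)
  fac <- names(table)[vapply(table, function(c)
    is.factor(c) || is.character(c), logical(1))]
  fac <- intersect(fac, all.vars(fixed))
  if (length(fac) >= 2) {
    tab <- table(table[fac])
    if (any(tab == 0)) {
      missing <- which(tab == 0, arr.ind = TRUE)
      combos <- apply(missing, 1, function(r)
        paste(mapply(function(d, i) dimnames(tab)[[d]][i],
                     seq_along(r), r), collapse = "/"))
      stop("missing cells: ", paste(combos, collapse = ", "))
    }
  }
  for (v in fac) if (!is.factor(table[[v]]))
    table[[v]] <- factor(table[[v]])
  X <- model.matrix(fixed, table)
  Z <- model.matrix(ranef, table)
  list(y = table[[outcome]], X = X, Z = Z,
       group = as.integer(factor(table$participant)),
       group_levels = levels(factor(table$participant)),
       data = table, fixed = fixed, ranef = ranef)
}

#' Block-level outcome table from a synthetic dataset
#'
#' One row per participant x condition x block with VCT, mean alpha and
#' beta power (dB), HbO amplitude and the fatigue state — the table the
#' hierarchical models operate on.
#'
#' @param dataset a `synthetic_dataset`
#' @return data frame
#' @export
block_table <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dataset$blocks
}

#' Model frame for a condition-by-block (optionally fatigue) model
#'
#' Extracts the post-baseline rows of the block table, attaches each
#' participant/condition's block-1 value of the outcome as the
#' `baseline` covariate, and converts condition/block/fatigue to
#' factors with sham / first post-baseline block / low fatigue as
#' reference levels.
#'
#' @param blocks a [block_table()]
#' @param outcome outcome column ("hbo", "alpha", "beta", or "vct")
#' @return data frame with columns `y`, `baseline`, `condition`,
#'   `block`, `fatigue`, `participant`
#' @export
model_frame <- function(blocks, outcome = "hbo") {
  stopifnot(outcome %in% names(blocks))
  base <- blocks[blocks$block == 1,
                 c("participant", "condition", outcome)]
  names(base)[3] <- "baseline"
  post <- blocks[blocks$block > 1, ]
  mf <- merge(post, base, by = c("participant", "condition"))
  data.frame(y = mf[[outcome]], baseline = mf$baseline,
             condition = factor(mf$condition, levels = c("sham", "trns")),
             block = factor(mf$block),
             fatigue = factor(mf$fatigue_state, levels = c("low", "high")),
             participant = mf$participant)
}

#' Stimulation-minus-sham change table
#'
#' Per participant/block/fatigue-state differences (tRNS - sham) of
#' HbO amplitude, alpha and beta power, and VCT. A cell contributes a
#' row only when the participant occupied the same fatigue state in
#' both conditions for that block; identical arms give an all-zero
#' change column.
#'
#' @param blocks a [block_table()]
#' @return data frame with `participant`, `block`, `fatigue`,
#'   `d_hbo`, `d_alpha`, `d_beta`, `d_vct`
#' @export
delta_table <- function(blocks) {
  sham <- blocks[blocks$condition == "sham", ]
  trns <- blocks[blocks$condition == "trns", ]
  m <- merge(sham, trns,
             by = c("participant", "block", "fatigue_state"),
             suffixes = c("_sham", "_trns"))
  data.frame(participant = m$participant, block = m$block,
             fatigue = factor(m$fatigue_state, levels = c("low", "high")),
             d_hbo = m$hbo_trns - m$hbo_sham,
             d_alpha = m$alpha_trns - m$alpha_sham,
             d_beta = m$beta_trns - m$beta_sham,
             d_vct = m$vct_trns - m$vct_sham)
}
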