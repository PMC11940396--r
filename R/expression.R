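EXPRESSION_GENES <- c("Hcn1", "Hcn2", "Hcn4", "Pitx2")

# Reported left-atrial expression (GAPDH-normalized, mean and SEM) used as
# simulation defaults: AF arm n = 7, control n = 5.
expression_defaults <- function() {
  data.frame(
    gene = EXPRESSION_GENES,
    af_mean = c(1.42, 1.39, 1.42, 1.22),
    af_sem = c(0.09, 0.03, 0.02, 0.04),
    ctrl_mean = c(1.48, 1.33, 1.35, 1.40),
    ctrl_sem = c(0.11, 0.01, 0.01, 0.04),
    stringsAsFactors = FALSE)
}

#' Simulate a raw qPCR-style expression table
#'
#' Draws per-animal GAPDH-normalized expression ratios from Gaussian group
#' distributions (SD recovered from the target SEM and group size), then
#' de-normalizes against simulated per-animal GAPDH levels so the output
#' looks like raw expression units, one row per (animal, gene) including
#' GAPDH itself.
#'
#' @param n_af,n_control Group sizes.
#' @param targets Data frame like \code{expression_defaults()} (per-gene
#'   group means and SEMs of the normalized ratio).
#' @param gapdh_meanlog,gapdh_sdlog Lognormal parameters of the simulated
#'   raw GAPDH level (arbitrary units).
#' @param seed Integer seed.
#' @return Data frame: animal, group, gene, raw_level.
#' @export
simulate_expression <- function(n_af = 7, n_control = 5,
                                targets = expression_defaults(),
                                gapdh_meanlog = log(10), gapdh_sdlog = 0.2,
                                seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (arm in c("control", "af")) {
      n <- if (arm == "af") n_af else n_control
      for (i in seq_len(n)) {
        animal <- paste0(if (arm == "af") "A" else "C", i)
        gapdh <- stats::rlnorm(1, gapdh_meanlog, gapdh_sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = animal, group = arm, gene = "GAPDH", raw_level = gapdh,
          stringsAsFactors = FALSE)
        for (g in seq_len(nrow(targets))) {
          mu <- if (arm == "af") targets$af_mean[g] else targets$ctrl_mean[g]
          sem <- if (arm == "af") targets$af_sem[g] else targets$ctrl_sem[g]
          ratio <- stats::rnorm(1, mu, sem * sqrt(n))
          rows[[length(rows) + 1L]] <- data.frame(
            animal = animal, group = arm, gene = targets$gene[g],
            raw_level = max(ratio, 0.01) * gapdh, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Housekeeping-normalized relative expression with group comparison
#'
#' Normalizes each target gene's raw level by the same animal's GAPDH
#' level (linear ratio; animals with missing or non-positive GAPDH are
#' excluded with a warning), then summarizes each gene per group as
#' mean +/- SEM and compares groups with Welch's t test.
#'
#' @param records Data frame with columns animal, group, gene, raw_level;
#'   must include a GAPDH row per animal.
#' @param method \code{"ratio"} (default) or \code{"ddct"}
#'   (2^-(Ct_gene - Ct_GAPDH) interpretation: raw levels treated as
#'   expression on a log2-ready scale via raw ratios of powers; provided
#'   for Ct-style inputs where raw_level holds 2^-Ct).
#' @return List of class \code{expression_result}: \code{records}
#'   (normalized per animal/gene), \code{summary} (per gene/group mean,
#'   sem, n), \code{tests} (per-gene Welch \code{test_result}), and
#'   \code{excluded} (animal ids dropped).
#' @export
relative_expression <- function(records, method = c("ratio", "ddct")) {
  method <- match.arg(method)
  stopifnot(all(c("animal", "group", "gene", "raw_level") %in% names(records)))
  gapdh <- records[records$gene == "GAPDH", , drop = FALSE]
  ref <- stats::setNames(gapdh$raw_level, gapdh$animal)
  animals <- unique(records$animal)
  bad <- animals[!(animals %in% names(ref)) |
                   !is.finite(ref[animals]) | ref[animals] <= 0]
  if (length(bad))
    warning("excluding animals without positive GAPDH: ",
            paste(bad, collapse = ", "))
  tgt <- records[records$gene != "GAPDH" & !(records$animal %in% bad), ,
                 drop = FALSE]
  tgt$normalized <- tgt$raw_level / ref[tgt$animal]
  if (method == "ddct")
    tgt$normalized <- 2^(log2(tgt$raw_level) - log2(ref[tgt$animal]))
  rownames(tgt) <- NULL
  genes <- unique(tgt$gene)
  summ <- list(); tests <- list()
  for (g in genes) {
    sub <- tgt[tgt$gene == g, , drop = FALSE]
    for (arm in unique(sub$group)) {
      v <- sub$normalized[sub$group == arm]
      summ[[length(summ) + 1L]] <- data.frame(
        gene = g, group = arm, n = length(v), mean = mean(v),
        sem = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
    }
    arms <- c(intersect(c("af", "control"), unique(sub$group)),
              setdiff(unique(sub$group), c("af", "control")))
    if (length(arms) == 2) {
      v1 <- sub$normalized[sub$group == arms[1]]
      v2 <- sub$normalized[sub$group == arms[2]]
      if (length(v1) >= 2 && length(v2) >= 2)
        tests[[g]] <- welch_t(v1, v2)
    }
  }
  structure(list(records = tgt, summary = do.call(rbind, summ),
                 tests = tests, excluded = as.character(bad)),
            class = "expression_result")
}
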