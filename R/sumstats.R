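#' Construct and validate a summary-statistics table
#'
#' The per-variant association summary for one trait from one source: effect
#' estimate (log-odds for binary traits), its standard error, the effect and
#' other alleles, and optionally the effect-allele frequency and sample size.
#' This is the object every downstream step consumes; validation is strict so
#' that estimation never sees a non-positive standard error or a duplicated
#' variant.
#'
#' @param df data.frame with columns snp_id, effect_allele, other_allele,
#'   beta, se, pvalue and optionally eaf, n
#' @param trait_label name of the trait the table describes
#' @return a `sumstats` data.frame (validated)
#' @export
sumstats <- function(df, trait_label = "trait") {
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("sumstats configuration error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$snp_id <- as.character(df$snp_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_

  problems <- character(0)
  bad_se <- df$snp_id[!is.finite(df$se) | df$se <= 0]
  if (length(bad_se) > 0) {
    problems <- c(problems, paste0("non-positive or missing se for: ",
                                   paste(bad_se, collapse = ", ")))
  }
  bad_p <- df$snp_id[!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1]
  if (length(bad_p) > 0) {
    problems <- c(problems, paste0("pvalue outside (0,1] for: ",
                                   paste(bad_p, collapse = ", ")))
  }
  dup <- unique(df$snp_id[duplicated(df$snp_id)])
  if (length(dup) > 0) {
    problems <- c(problems, paste0("duplicated snp_id: ",
                                   paste(dup, collapse = ", ")))
  }
  valid_alleles <- c("A", "C", "G", "T")
  bad_al <- df$snp_id[!(df$effect_allele %in% valid_alleles) |
                        !(df$other_allele %in% valid_alleles) |
                        df$effect_allele == df$other_allele]
  if (length(bad_al) > 0) {
    problems <- c(problems, paste0("invalid allele pair for: ",
                                   paste(bad_al, collapse = ", ")))
  }
  bad_eaf <- df$snp_id[!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)]
  if (length(bad_eaf) > 0) {
    problems <- c(problems, paste0("eaf outside [0,1] for: ",
                                   paste(bad_eaf, collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("sumstats validation error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  attr(df, "trait_label") <- trait_label
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Read a summary-statistics table from delimited text
#'
#' @param path delimited text file with a header (tab or comma separated,
#'   auto-detected)
#' @param dialect named character vector mapping canonical field names
#'   (snp_id, effect_allele, other_allele, eaf, beta, se, pvalue, n) onto the
#'   file's column names. The default reads the canonical header
#'   SNP/EA/OA/EAF/BETA/SE/P/N.
#' @param trait_label trait name recorded on the table
#' @return a validated [sumstats] table
#' @export
read_sumstats <- function(path,
                          dialect = c(snp_id = "SNP", effect_allele = "EA",
                                      other_allele = "OA", eaf = "EAF",
                                      beta = "BETA", se = "SE", pvalue = "P",
                                      n = "N"),
                          trait_label = "trait") {
  raw <- data.table::fread(path, data.table = FALSE)
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  need <- dialect[intersect(names(dialect), c(mandatory, "eaf", "n"))]
  absent <- need[mandatory][!need[mandatory] %in% names(raw)]
  if (length(absent) > 0) {
    stop("read_sumstats configuration error: file ", path,
         " lacks column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(snp_id = raw[[dialect[["snp_id"]]]],
                    effect_allele = raw[[dialect[["effect_allele"]]]],
                    other_allele = raw[[dialect[["other_allele"]]]],
                    beta = raw[[dialect[["beta"]]]],
                    se = raw[[dialect[["se"]]]],
                    pvalue = raw[[dialect[["pvalue"]]]],
                    stringsAsFactors = FALSE)
  if ("eaf" %in% names(dialect) && dialect[["eaf"]] %in% names(raw)) {
    out$eaf <- raw[[dialect[["eaf"]]]]
  }
  if ("n" %in% names(dialect) && dialect[["n"]] %in% names(raw)) {
    out$n <- raw[[dialect[["n"]]]]
  }
  sumstats(out, trait_label = trait_label)
}

#' Write a summary-statistics table with the canonical header
#'
#' @param ss a [sumstats] table
#' @param path output file (tab separated)
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp_id, EA = ss$effect_allele,
                    OA = ss$other_allele, EAF = ss$eaf, BETA = ss$beta,
                    SE = ss$se, P = ss$pvalue, N = ss$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an LD matrix object
#'
#' @param r2 symmetric square matrix of squared correlations, unit diagonal
#' @param snp_ids variant identifiers for rows/columns
#' @return an `ld_matrix` object
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("ld_matrix requires snp ids", call. = FALSE)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids)) {
    stop("ld_matrix must be square with one id per row", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("ld_matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("ld_matrix diagonal must be 1", call. = FALSE)
  if (any(r2 < -1e-8) || any(r2 > 1 + 1e-8)) {
    stop("ld_matrix values must lie in [0,1]", call. = FALSE)
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2),
            class = "ld_matrix")
}

#' Read an LD matrix from delimited text (ids as header row and first column)
#' @param path delimited square matrix file
#' @return an [ld_matrix]
#' @export
read_ld_matrix <- function(path) {
  raw <- data.table::fread(path, data.table = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  ld_matrix(m, ids)
}

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "G" & oa == "C") | (ea == "C" & oa == "G")
}

.complement <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

# Align one table's alleles to reference alleles. Returns per-row action:
# "none", "flip", or "drop:<reason>".
.align_alleles <- function(ref_ea, ref_oa, ea, oa, eaf, palindrome_policy,
                           eaf_window = c(0.42, 0.58)) {
  n <- length(ea)
  action <- rep("none", n)
  pal <- .is_palindromic(ea, oa)
  same <- ea == ref_ea & oa == ref_oa
  swap <- ea == ref_oa & oa == ref_ea
  csame <- .complement(ea) == ref_ea & .complement(oa) == ref_oa
  cswap <- .complement(ea) == ref_oa & .complement(oa) == ref_ea
  action[swap & !same] <- "flip"
  # non-palindromic strand flips resolve unambiguously by letters
  action[!pal & !same & !swap & csame] <- "none"
  action[!pal & !same & !swap & !csame & cswap] <- "flip"
  irreconcilable <- !same & !swap & !csame & !cswap
  action[irreconcilable] <- "drop:alleles_irreconcilable"
  if (palindrome_policy == "strict") {
    action[pal] <- "drop:palindromic_strict"
  } else if (palindrome_policy == "drop_ambiguous") {
    ambiguous <- pal & (is.na(eaf) |
                          (eaf >= eaf_window[1] & eaf <= eaf_window[2]))
    action[ambiguous] <- "drop:palindromic_ambiguous_eaf"
  } # "keep": palindromes aligned by letters as-is
  action
}

#' Harmonize exposure and outcome tables into one analysis dataset
#'
#' Inner-joins one or more exposure tables with an outcome table on variant
#' id and aligns every effect to the first exposure's effect allele. Where a
#' table's effect allele equals the reference other allele (directly or after
#' strand complement), its beta sign is flipped and eaf replaced by 1 - eaf.
#' Allele pairs that cannot be reconciled are dropped and logged, never
#' silently discarded. Palindromic (A/T, G/C) variants are handled per
#' policy: the default drops them when eaf is missing or near 0.5 (within
#' the ambiguity window), since strand cannot then be resolved.
#'
#' @param exposure_tables a [sumstats] table or list of them (K exposures)
#' @param outcome_table a [sumstats] table
#' @param palindrome_policy "drop_ambiguous" (default), "strict" (drop all
#'   palindromes), or "keep"
#' @param eaf_window ambiguity window for palindrome eaf, default c(0.42, 0.58)
#' @return an `mr_dataset`: list with snp_ids, exposure_beta / exposure_se /
#'   exposure_pvalue (p x K matrices), outcome_beta, outcome_se (length p),
#'   orientation log, drop log and meta
#' @export
harmonize <- function(exposure_tables, outcome_table,
                      palindrome_policy = c("drop_ambiguous", "strict", "keep"),
                      eaf_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (inherits(exposure_tables, "sumstats")) exposure_tables <- list(exposure_tables)
  stopifnot(length(exposure_tables) >= 1)
  # missing eaf anywhere forces strict palindrome handling
  if (palindrome_policy == "drop_ambiguous") {
    any_missing_eaf <- any(vapply(c(exposure_tables, list(outcome_table)),
                                  function(t) all(is.na(t$eaf)), logical(1)))
    if (any_missing_eaf) palindrome_policy <- "strict"
  }

  ref <- exposure_tables[[1]]
  ids <- ref$snp_id
  for (t in exposure_tables[-1]) ids <- intersect(ids, t$snp_id)
  ids <- intersect(ids, outcome_table$snp_id)
  if (length(ids) == 0) {
    stop("harmonize: empty intersection of snp ids across tables", call. = FALSE)
  }

  K <- length(exposure_tables)
  ref_rows <- ref[match(ids, ref$snp_id), ]
  drop_log <- data.frame(snp_id = character(0), table = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  orientation <- data.frame(snp_id = ids, stringsAsFactors = FALSE)
  keep <- rep(TRUE, length(ids))

  exposure_beta <- exposure_se <- exposure_pvalue <- matrix(
    NA_real_, length(ids), K)
  traits <- character(K)
  aligned <- vector("list", K + 1)

  tables <- c(exposure_tables, list(outcome_table))
  labels <- c(paste0("exposure", seq_len(K)), "outcome")
  for (i in seq_along(tables)) {
    tab <- tables[[i]][match(ids, tables[[i]]$snp_id), ]
    if (i == 1) {
      action <- rep("none", length(ids))
      # reference table: still apply the palindrome policy to itself
      pal <- .is_palindromic(tab$effect_allele, tab$other_allele)
      if (palindrome_policy == "strict") {
        action[pal] <- "drop:palindromic_strict"
      } else if (palindrome_policy == "drop_ambiguous") {
        amb <- pal & (is.na(tab$eaf) |
                        (tab$eaf >= eaf_window[1] & tab$eaf <= eaf_window[2]))
        action[amb] <- "drop:palindromic_ambiguous_eaf"
      }
    } else {
      action <- .align_alleles(ref_rows$effect_allele, ref_rows$other_allele,
                               tab$effect_allele, tab$other_allele, tab$eaf,
                               palindrome_policy, eaf_window)
    }
    flip <- action == "flip"
    tab$beta[flip] <- -tab$beta[flip]
    tab$eaf[flip] <- 1 - tab$eaf[flip]
    dropped <- startsWith(action, "drop:")
    if (any(dropped)) {
      drop_log <- rbind(drop_log, data.frame(
        snp_id = ids[dropped], table = labels[i],
        reason = sub("^drop:", "", action[dropped]), stringsAsFactors = FALSE))
      keep <- keep & !dropped
    }
    orientation[[labels[i]]] <- ifelse(dropped, "drop", action)
    aligned[[i]] <- tab
  }

  if (!any(keep)) {
    stop("harmonize: no snp survives allele reconciliation", call. = FALSE)
  }
  for (k in seq_len(K)) {
    exposure_beta[, k] <- aligned[[k]]$beta
    exposure_se[, k] <- aligned[[k]]$se
    exposure_pvalue[, k] <- aligned[[k]]$pvalue
    traits[k] <- attr(exposure_tables[[k]], "trait_label") %||% paste0("exposure", k)
  }
  out_tab <- aligned[[K + 1]]

  structure(list(
    snp_ids = ids[keep],
    exposure_beta = exposure_beta[keep, , drop = FALSE],
    exposure_se = exposure_se[keep, , drop = FALSE],
    exposure_pvalue = exposure_pvalue[keep, , drop = FALSE],
    exposure_eaf = ref_rows$eaf[keep],
    effect_allele = ref_rows$effect_allele[keep],
    other_allele = ref_rows$other_allele[keep],
    outcome_beta = out_tab$beta[keep],
    outcome_se = out_tab$se[keep],
    orientation = orientation[keep, , drop = FALSE],
    drop_log = drop_log,
    meta = list(exposure_traits = traits,
                outcome_trait = attr(outcome_table, "trait_label") %||% "outcome",
                palindrome_policy = palindrome_policy,
                p_threshold = NA_real_, clump_r2 = NA_real_)
  ), class = "mr_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of variants / exposures in an mr_dataset
#' @param ds an `mr_dataset`
#' @export
n_snps <- function(ds) length(ds$snp_ids)

#' @rdname n_snps
#' @export
n_exposures <- function(ds) ncol(ds$exposure_beta)

#' Subset an mr_dataset by variant index or id
#' @param ds an `mr_dataset`
#' @param idx integer or logical index, or character snp ids
#' @export
subset_snps <- function(ds, idx) {
  if (is.character(idx)) idx <- match(idx, ds$snp_ids)
  ds$snp_ids <- ds$snp_ids[idx]
  ds$exposure_beta <- ds$exposure_beta[idx, , drop = FALSE]
  ds$exposure_se <- ds$exposure_se[idx, , drop = FALSE]
  ds$exposure_pvalue <- ds$exposure_pvalue[idx, , drop = FALSE]
  ds$exposure_eaf <- ds$exposure_eaf[idx]
  ds$effect_allele <- ds$effect_allele[idx]
  ds$other_allele <- ds$other_allele[idx]
  ds$outcome_beta <- ds$outcome_beta[idx]
  ds$outcome_se <- ds$outcome_se[idx]
  ds$orientation <- ds$orientation[idx, , drop = FALSE]
  ds
}

#' Export one side of an mr_dataset back to a sumstats table
#' @param ds an `mr_dataset`
#' @param which "exposure" (optionally with `k`) or "outcome"
#' @param k exposure index
#' @export
as_sumstats <- function(ds, which = c("exposure", "outcome"), k = 1) {
  which <- match.arg(which)
  if (which == "exposure") {
    df <- data.frame(snp_id = ds$snp_ids, effect_allele = ds$effect_allele,
                     other_allele = ds$other_allele, eaf = ds$exposure_eaf,
                     beta = ds$exposure_beta[, k], se = ds$exposure_se[, k],
                     pvalue = ds$exposure_pvalue[, k],
                     stringsAsFactors = FALSE)
    sumstats(df, trait_label = ds$meta$exposure_traits[k])
  } else {
    df <- data.frame(snp_id = ds$snp_ids, effect_allele = ds$effect_allele,
                     other_allele = ds$other_allele, eaf = ds$exposure_eaf,
                     beta = ds$outcome_beta, se = ds$outcome_se,
                     pvalue = 2 * stats::pnorm(-abs(ds$outcome_beta / ds$outcome_se)),
                     stringsAsFactors = FALSE)
    sumstats(df, trait_label = ds$meta$outcome_trait)
  }
}

#' Greedy LD clumping
#'
#' Orders variants by ascending p-value (ties broken lexicographically by
#' snp_id), keeps the best remaining variant and removes all others with
#' squared correlation above the threshold to any kept variant.
#'
#' @param table a [sumstats] table
#' @param ld an [ld_matrix] covering all variants in `table`
#' @param r2_threshold keep threshold on squared correlation (default 0.001)
#' @param tie_break only "snp_id" (lexicographic) is implemented
#' @return character vector of kept snp ids, in kept order
#' @export
clump <- function(table, ld, r2_threshold = 0.001, tie_break = "snp_id") {
  absent <- setdiff(table$snp_id, ld$snp_ids)
  if (length(absent) > 0) {
    stop("clump: snp(s) absent from LD matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ord <- order(table$pvalue, table$snp_id)
  candidates <- table$snp_id[ord]
  kept <- character(0)
  while (length(candidates) > 0) {
    best <- candidates[1]
    kept <- c(kept, best)
    r2 <- ld$r2[best, candidates]
    candidates <- candidates[r2 <= r2_threshold & candidates != best]
  }
  kept
}

#' Select instruments by exposure p-value threshold
#'
#' Subsets a harmonized dataset to variants whose first-exposure p-value is
#' below the threshold, recording the threshold and the number of retained
#' genome-wide-significant (p < 5e-8) members in the metadata.
#'
#' @param ds an `mr_dataset`
#' @param p_threshold selection threshold (default 1e-4; use 5e-8 for a
#'   classical genome-wide-significant instrument set)
#' @return the subsetted `mr_dataset`
#' @export
select_instruments <- function(ds, p_threshold = 1e-4) {
  keep <- ds$exposure_pvalue[, 1] < p_threshold
  if (!any(keep)) {
    stop("select_instruments: no snp passes p < ", format(p_threshold),
         "; consider relaxing the threshold", call. = FALSE)
  }
  out <- subset_snps(ds, which(keep))
  out$meta$p_threshold <- p_threshold
  out$meta$n_genomewide_significant <-
    sum(out$exposure_pvalue[, 1] < 5e-8)
  out
}

#' Write a harmonized dataset and its provenance side-car
#' @param ds an `mr_dataset`
#' @param path base path; writes `<path>.tsv` and `<path>.provenance.yaml`
#' @export
write_mr_dataset <- function(ds, path) {
  K <- n_exposures(ds)
  tab <- data.frame(SNP = ds$snp_ids, EA = ds$effect_allele,
                    OA = ds$other_allele, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    tab[[paste0("BETA_X", k)]] <- ds$exposure_beta[, k]
    tab[[paste0("SE_X", k)]] <- ds$exposure_se[, k]
    tab[[paste0("P_X", k)]] <- ds$exposure_pvalue[, k]
  }
  tab$BETA_Y <- ds$outcome_beta
  tab$SE_Y <- ds$outcome_se
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- ds$meta
  prov$n_snps <- n_snps(ds)
  prov$dropped <- if (nrow(ds$drop_log) > 0) {
    paste(ds$drop_log$snp_id, ds$drop_log$reason, sep = ":")
  } else "none"
  yaml::write_yaml(prov, paste0(path, ".provenance.yaml"))
  invisible(path)
}

#' Assemble an mr_dataset directly from aligned numeric columns
#'
#' Convenience constructor for simulated or already-harmonized inputs where
#' all tables share effect alleles.
#'
#' @param snp_ids variant ids
#' @param exposure_beta,exposure_se p x K matrices (vectors accepted for K=1)
#' @param outcome_beta,outcome_se length-p vectors
#' @param exposure_pvalue optional matrix; computed from Wald z if omitted
#' @param exposure_traits,outcome_trait labels
#' @export
mr_dataset <- function(snp_ids, exposure_beta, exposure_se, outcome_beta,
                       outcome_se, exposure_pvalue = NULL,
                       exposure_traits = NULL, outcome_trait = "outcome") {
  exposure_beta <- as.matrix(exposure_beta)
  exposure_se <- as.matrix(exposure_se)
  p <- length(snp_ids)
  K <- ncol(exposure_beta)
  stopifnot(nrow(exposure_beta) == p, all(dim(exposure_se) == c(p, K)),
            length(outcome_beta) == p, length(outcome_se) == p)
  if (any(exposure_se <= 0) || any(outcome_se <= 0)) {
    stop("mr_dataset: standard errors must be strictly positive", call. = FALSE)
  }
  if (is.null(exposure_pvalue)) {
    exposure_pvalue <- 2 * stats::pnorm(-abs(exposure_beta / exposure_se))
  }
  if (is.null(exposure_traits)) exposure_traits <- paste0("exposure", seq_len(K))
  structure(list(
    snp_ids = as.character(snp_ids),
    exposure_beta = exposure_beta, exposure_se = exposure_se,
    exposure_pvalue = as.matrix(exposure_pvalue),
    exposure_eaf = rep(NA_real_, p),
    effect_allele = rep("A", p), other_allele = rep("G", p),
    outcome_beta = as.numeric(outcome_beta),
    outcome_se = as.numeric(outcome_se),
    orientation = data.frame(snp_id = as.character(snp_ids),
                             exposure1 = "none", outcome = "none",
                             stringsAsFactors = FALSE),
    drop_log = data.frame(snp_id = character(0), table = character(0),
                          reason = character(0), stringsAsFactors = FALSE),
    meta = list(exposure_traits = exposure_traits,
                outcome_trait = outcome_trait,
                palindrome_policy = "none",
                p_threshold = NA_real_, clump_r2 = NA_real_)
  ), class = "mr_dataset")
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat("mr_dataset:", n_snps(x), "variants,", n_exposures(x), "exposure(s)\n")
  cat("  exposures:", paste(x$meta$exposure_traits, collapse = ", "), "\n")
  cat("  outcome:  ", x$meta$outcome_trait, "\n")
  if (!is.na(x$meta$p_threshold)) {
    cat("  selection: p <", format(x$meta$p_threshold), "\n")
  }
  invisible(x)
}
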