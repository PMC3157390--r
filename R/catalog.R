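# Curation of a GWAS-catalog-style association list into a testable set:
# p-value/effect/ancestry filters, deduplication, LD pruning, proxy-SNP
# selection against the genotyping platform, and strand checks.

CATALOG_COLUMNS <- c("snp_id", "phenotype", "risk_allele", "other_allele",
                     "raf", "effect", "trait_type", "p_value", "ancestry",
                     "study_id", "n_cases", "n_controls", "single_snp",
                     "includes_cohort")

#' Read an association catalog
#'
#' Tab-separated, one row per published association, \code{"."} for
#' missing values. Columns: \code{snp_id}, \code{phenotype},
#' \code{risk_allele}, \code{other_allele}, \code{raf}, \code{effect},
#' \code{trait_type} (\code{binary}/\code{quantitative}), \code{p_value},
#' \code{ancestry}, \code{study_id}, \code{n_cases}, \code{n_controls},
#' \code{single_snp}, \code{includes_cohort}.
#'
#' @param path Path to the TSV file.
#' @return Data frame with typed columns; rows with unparseable p-values
#'   or effects raise an error naming the offending row.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, na.strings = ".", colClasses = "character",
                          check.names = FALSE)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing_cols))
    stop("catalog is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(x))
    if (length(bad))
      stop("catalog row ", bad[1], ": malformed ", col, " '",
           df[[col]][bad[1]], "'", call. = FALSE)
    x
  }
  df$raf <- num("raf")
  df$effect <- num("effect")
  df$p_value <- num("p_value")
  df$n_cases <- as.integer(num("n_cases"))
  df$n_controls <- as.integer(num("n_controls"))
  df$single_snp <- df$single_snp %in% c("TRUE", "true", "1", "yes")
  df$includes_cohort <- df$includes_cohort %in% c("TRUE", "true", "1", "yes")
  bad_p <- which(!is.na(df$p_value) & (df$p_value <= 0 | df$p_value > 1))
  if (length(bad_p))
    stop("catalog row ", bad_p[1], ": p-value out of (0, 1]", call. = FALSE)
  df
}

#' Read a pairwise LD table
#'
#' Columns \code{snp_a}, \code{snp_b}, \code{r2}. Pairs are unordered;
#' missing pairs are treated as r-squared 0 throughout the package.
#'
#' @param path Path to the TSV file.
#' @return Data frame with character SNP ids and numeric \code{r2}.
#' @export
read_ld_table <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric"))
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(df)),
            all(df$r2 >= 0 & df$r2 <= 1))
  df
}

#' Read a genotyping platform manifest
#'
#' Columns \code{snp_id}, \code{call_rate}; SNPs absent from the manifest
#' are off-platform.
#'
#' @param path Path to the TSV file.
#' @return Data frame with \code{snp_id} and \code{call_rate}.
#' @export
read_platform_manifest <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "numeric"))
  stopifnot(all(c("snp_id", "call_rate") %in% names(df)),
            all(df$call_rate >= 0 & df$call_rate <= 1))
  df
}

ld_lookup <- function(ld, a, b) {
  hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
  if (any(hit)) max(ld$r2[hit]) else 0
}

#' Filter catalog entries for replication eligibility
#'
#' Keeps associations with a reported p-value at or below \code{p_max}
#' (guards against false positives in the source list), a reported odds
#' ratio or regression coefficient, single-SNP (not haplotype) status,
#' European discovery ancestry, and no overlap with the replication
#' cohort itself.
#'
#' @param entries Catalog data frame (see [read_catalog()]).
#' @param p_max Largest admissible discovery p-value, default 1e-7.
#' @return The retained rows, with a \code{drop_reason} attribute-free
#'   companion available via \code{attr(, "dropped")} (rows plus reason).
#' @export
filter_entries <- function(entries, p_max = 1e-7) {
  reason <- rep(NA_character_, nrow(entries))
  reason[is.na(entries$p_value) | entries$p_value > p_max] <- "p_above_threshold"
  reason[is.na(reason) & is.na(entries$effect)] <- "no_effect_size"
  reason[is.na(reason) & !entries$single_snp] <- "haplotype_association"
  reason[is.na(reason) & entries$ancestry != "European"] <- "non_european"
  reason[is.na(reason) & entries$includes_cohort] <- "includes_cohort"
  kept <- entries[is.na(reason), , drop = FALSE]
  dropped <- entries[!is.na(reason), , drop = FALSE]
  dropped$drop_reason <- reason[!is.na(reason)]
  attr(kept, "dropped") <- dropped
  kept
}

#' Deduplicate associations reported by several studies
#'
#' One survivor per (SNP, phenotype): the study with the largest number
#' of cases; ties broken by smaller p-value, then lexicographic study id,
#' so the result is deterministic.
#'
#' @param entries Catalog data frame.
#' @return Deduplicated data frame (input order of survivors preserved).
#' @export
deduplicate_entries <- function(entries) {
  if (nrow(entries) < 2) return(entries)
  key <- paste(entries$snp_id, entries$phenotype, sep = "\r")
  ord <- order(key, -entries$n_cases, entries$p_value, entries$study_id)
  first <- ord[!duplicated(key[ord])]
  entries[sort(first), , drop = FALSE]
}

#' Prune associations in linkage disequilibrium
#'
#' Within each phenotype, SNPs are grouped into connected components of
#' the graph linking pairs with r-squared at or above \code{r2_block},
#' and one association is kept per component: within a single study the
#' smallest p-value wins; across studies the largest case count wins
#' (then smallest p, then study id). Missing LD pairs count as
#' independent.
#'
#' @param entries Catalog data frame (post-deduplication).
#' @param ld LD table (see [read_ld_table()]).
#' @param r2_block Blocking threshold, default 0.1.
#' @return Pruned data frame.
#' @export
prune_ld <- function(entries, ld, r2_block = 0.1) {
  if (nrow(entries) < 2) return(entries)
  keep <- logical(nrow(entries))
  for (ph in unique(entries$phenotype)) {
    idx <- which(entries$phenotype == ph)
    snps <- unique(entries$snp_id[idx])
    comp <- ld_components(snps, ld, r2_block)
    for (members in comp) {
      rows <- idx[entries$snp_id[idx] %in% members]
      sub <- entries[rows, , drop = FALSE]
      single_study <- length(unique(sub$study_id)) == 1
      ord <- if (single_study)
        order(sub$p_value, sub$study_id)
      else
        order(-sub$n_cases, sub$p_value, sub$study_id)
      keep[rows[ord[1]]] <- TRUE
    }
  }
  entries[keep, , drop = FALSE]
}

# connected components of the r2 >= threshold graph over `snps`
ld_components <- function(snps, ld, r2_block) {
  edges <- ld[ld$r2 >= r2_block &
                ld$snp_a %in% snps & ld$snp_b %in% snps, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[c("snp_a", "snp_b")], directed = FALSE,
    vertices = data.frame(name = snps))
  membership <- igraph::components(g)$membership
  split(names(membership), membership)
}

#' Choose the SNP actually tested for an association
#'
#' The reported SNP is used when it is on the platform with a call rate
#' of at least \code{call_min}; otherwise the highest-r2 proxy with
#' r-squared at or above \code{r2_proxy} is substituted; with no such
#' proxy the association is dropped (a recorded outcome, not an error).
#'
#' @param entries Catalog data frame.
#' @param platform Platform manifest (see [read_platform_manifest()]).
#' @param ld LD table providing candidate proxies.
#' @param r2_proxy Minimum proxy r-squared, default 0.5.
#' @param call_min Minimum call rate, default 0.99.
#' @return Data frame of curated associations with columns
#'   \code{test_snp} and \code{proxy_r2} added; dropped rows (with
#'   \code{drop_reason}) in \code{attr(, "dropped")}.
#' @export
select_proxies <- function(entries, platform, ld, r2_proxy = 0.5,
                           call_min = 0.99) {
  test_snp <- character(nrow(entries))
  proxy_r2 <- numeric(nrow(entries))
  reason <- rep(NA_character_, nrow(entries))
  for (i in seq_len(nrow(entries))) {
    snp <- entries$snp_id[i]
    j <- match(snp, platform$snp_id)
    if (!is.na(j) && platform$call_rate[j] >= call_min) {
      test_snp[i] <- snp
      proxy_r2[i] <- 1
      next
    }
    cand <- ld[(ld$snp_a == snp | ld$snp_b == snp) & ld$r2 >= r2_proxy, ,
               drop = FALSE]
    if (nrow(cand)) {
      cand$partner <- ifelse(cand$snp_a == snp, cand$snp_b, cand$snp_a)
      j2 <- match(cand$partner, platform$snp_id)
      usable <- !is.na(j2) & platform$call_rate[j2] >= call_min &
        cand$partner != snp
      cand <- cand[usable, , drop = FALSE]
    }
    if (nrow(cand)) {
      best <- order(-cand$r2, cand$partner)[1]  # deterministic on tie
      test_snp[i] <- cand$partner[best]
      proxy_r2[i] <- cand$r2[best]
    } else {
      reason[i] <- "no_platform_snp_or_proxy"
    }
  }
  kept <- entries[is.na(reason), , drop = FALSE]
  kept$test_snp <- test_snp[is.na(reason)]
  kept$proxy_r2 <- proxy_r2[is.na(reason)]
  dropped <- entries[!is.na(reason), , drop = FALSE]
  dropped$drop_reason <- reason[!is.na(reason)]
  attr(kept, "dropped") <- dropped
  kept
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Check strand consistency of a reported risk allele
#'
#' Publications differ in stranding conventions, so the reported
#' risk-allele frequency is compared with the frequency of that allele in
#' a reference panel. Frequencies are judged to match when both are below
#' 0.35 or both above 0.65 (frequencies at exactly 0.35/0.65 do not
#' match). Unambiguous SNPs (allele pair not a reverse complement) with
#' matching frequencies are \code{confirmed}; ambiguous SNPs (A/T or
#' C/G), SNPs without reference frequency, and frequency mismatches go to
#' \code{manual_review}; entries named in \code{unresolvable} (risk
#' allele not recoverable from the source) are \code{undetermined} and
#' must be excluded from testing.
#'
#' @param risk_allele,other_allele Single-base alleles (A/C/G/T),
#'   vectorized.
#' @param raf Reported risk-allele frequency in controls.
#' @param reference_freq Reference-panel frequency of the risk allele
#'   (NA when the panel lacks the SNP).
#' @param unresolvable Logical vector (or single flag) marking entries
#'   the analyst has declared unresolvable.
#' @return Character vector: \code{confirmed}, \code{manual_review} or
#'   \code{undetermined}.
#' @export
check_strand <- function(risk_allele, other_allele, raf, reference_freq,
                         unresolvable = FALSE) {
  ok <- risk_allele %in% names(COMPLEMENT) &
    other_allele %in% names(COMPLEMENT)
  if (!all(ok))
    stop("invalid allele character in rows: ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  n <- length(risk_allele)
  unresolvable <- rep_len(unresolvable, n)
  ambiguous <- COMPLEMENT[risk_allele] == other_allele
  match_lo <- !is.na(raf) & !is.na(reference_freq) &
    raf < 0.35 & reference_freq < 0.35
  match_hi <- !is.na(raf) & !is.na(reference_freq) &
    raf > 0.65 & reference_freq > 0.65
  status <- ifelse(!ambiguous & (match_lo | match_hi),
                   "confirmed", "manual_review")
  status[unresolvable] <- "undetermined"
  unname(status)
}

#' Full catalog curation pipeline
#'
#' Applies, in order: eligibility filters, deduplication, LD pruning,
#' proxy selection, and strand checking. Strand \code{manual_review}
#' entries are retained in the curated output (flagged for the analyst);
#' \code{undetermined} entries are removed from testing.
#'
#' @param catalog Catalog data frame (see [read_catalog()]).
#' @param ld LD table.
#' @param platform Platform manifest.
#' @param reference_freqs Named numeric vector: reference-panel frequency
#'   of the reported risk allele by SNP id (NA/absent means no data).
#' @param unresolvable Character vector of SNP ids whose risk allele
#'   cannot be determined from the source publication.
#' @param p_max,r2_block,r2_proxy,call_min Thresholds as in the stage
#'   functions.
#' @return List with data frames \code{curated} (with \code{test_snp},
#'   \code{proxy_r2}, \code{strand_status}), \code{dropped} (with
#'   \code{drop_reason}) and \code{review} (the manual-review subset).
#' @export
curate_catalog <- function(catalog, ld, platform,
                           reference_freqs = NULL,
                           unresolvable = character(),
                           p_max = 1e-7, r2_block = 0.1,
                           r2_proxy = 0.5, call_min = 0.99) {
  drop_cols <- function(df) df[setdiff(names(df), "drop_reason")]
  dropped <- list()

  kept <- filter_entries(catalog, p_max)
  dropped$filter <- attr(kept, "dropped")
  kept <- deduplicate_entries(kept)
  kept <- prune_ld(kept, ld, r2_block)
  kept <- select_proxies(kept, platform, ld, r2_proxy, call_min)
  dropped$proxy <- attr(kept, "dropped")

  ref <- if (is.null(reference_freqs)) rep(NA_real_, nrow(kept))
         else unname(reference_freqs[kept$snp_id])
  kept$strand_status <- check_strand(kept$risk_allele, kept$other_allele,
                                     kept$raf, ref,
                                     kept$snp_id %in% unresolvable)
  undet <- kept$strand_status == "undetermined"
  if (any(undet)) {
    d <- kept[undet, , drop = FALSE]
    d$drop_reason <- "strand_undetermined"
    dropped$strand <- drop_cols(d)[names(catalog)]
    dropped$strand$drop_reason <- "strand_undetermined"
  }
  curated <- kept[!undet, , drop = FALSE]
  attr(curated, "dropped") <- NULL
  all_dropped <- do.call(rbind, Filter(Negate(is.null), unname(dropped)))
  list(curated = curated,
       dropped = if (is.null(all_dropped))
         cbind(catalog[0, ], drop_reason = character(0)) else all_dropped,
       review = curated[curated$strand_status == "manual_review", ,
                        drop = FALSE])
}
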