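#' Generate a complete synthetic NC-II study
#'
#' Builds a scaled-down but structurally complete testcross study: an inbred
#' maternal panel and a small tester set with block LD, the full factorial
#' design, F1 genotypes derived with [infer_f1_genotypes()], multi-environment
#' phenotypes for parents and hybrids, and a ground-truth table of the planted
#' QTLs. Three traits emulate the canonical architectures:
#' \itemize{
#'   \item \strong{DTT} (days to tasseling): three additive QTLs of
#'     decreasing effect, expressed identically in lines and hybrids - the
#'     additive (M, F1) detection pattern, with MPH exactly cancelling.
#'   \item \strong{PH} (plant height): one dominant QTL (all testers carry the
#'     complementing allele, so the locus is flat in hybrids but segregates in
#'     the maternal panel and in MPH) and one epistatically masked QTL pair:
#'     the masker is fixed for the repressive allele in the maternal pool and
#'     for the activating allele in the testers, so the masked locus is silent
#'     in maternal lines and expressed in every hybrid.
#'   \item \strong{EW} (ear weight): several small masked (epistatic) effects
#'     plus one small additive QTL.
#' }
#' Phenotypes add a line-level polygenic deviate and per-plot noise across
#' `n_locations` x `n_years` environments with additive location and year
#' effects, on absolute trait scales (positive intercepts) so that mid-parent
#' heterosis is well defined.
#'
#' @param seed Integer seed.
#' @param n_maternal,n_testers Panel sizes.
#' @param n_variants Marker count (spread over `n_chrom` chromosomes).
#' @param n_chrom Chromosomes.
#' @param rho Within-block latent LD coefficient.
#' @param n_locations,n_years Environments.
#' @param scale Multiplier applied to panel sizes (a crude scale factor for
#'   smoke tests).
#' @return List of class `nc2_study`: `parents`, `design`, `f1`
#'   ([geno_matrix()]s and [enumerate_crosses()] design), `pheno_parents`,
#'   `pheno_f1` (long trait tables), `truth` (planted-QTL table), `traits`.
#' @export
gen_full_study <- function(seed = 1L, n_maternal = 300L, n_testers = 5L,
                           n_variants = 1200L, n_chrom = 10L, rho = 0.985,
                           n_locations = 3L, n_years = 2L, scale = 1) {
  set.seed(seed)
  n_maternal <- max(20L, as.integer(n_maternal * scale))
  n_par <- n_maternal + n_testers
  # marker density relative to LD reach mirrors a dense resequencing panel:
  # tens of markers tag each causal locus
  block_len <- 40L
  parents <- gen_inbred_genotypes(n_par, n_variants, block_len = block_len,
                                  rho = rho, het_rate = 0.002,
                                  n_chrom = n_chrom, spacing_bp = 50000L)
  maternal_ids <- sprintf("M%04d", seq_len(n_maternal))
  tester_ids <- sprintf("T%02d", seq_len(n_testers))
  rownames(parents$dosages) <- c(maternal_ids, tester_ids)

  per_chrom <- ceiling(n_variants / n_chrom)
  # causal markers sit at LD-block centers so both flanks tag them; slot 1 is
  # the first block of the chromosome, slot 2 the third (or mid-chromosome on
  # small maps)
  off1 <- min(per_chrom - 1L, block_len %/% 2L)
  off2 <- min(per_chrom - 1L, 2L * block_len + block_len %/% 2L)
  if (off2 <= off1) off2 <- max(2L, per_chrom %/% 2L)
  causal_at <- function(chrom, slot = 1L) {
    (chrom - 1L) * per_chrom + if (slot == 1L) off1 else off2
  }
  loci <- list(
    dtt1 = causal_at(1L), dtt2 = causal_at(4L), dtt3 = causal_at(8L),
    ph_dom = causal_at(2L), ph_maskerA = causal_at(3L),
    ph_maskedB = causal_at(6L),
    ew_add = causal_at(5L),
    ew_m1 = causal_at(7L), ew_m2 = causal_at(9L), ew_m3 = causal_at(10L),
    ew_m4 = causal_at(3L, 2L), ew_m5 = causal_at(6L, 2L),
    ew_m6 = causal_at(9L, 2L)
  )
  D <- parents$dosages
  mi <- seq_len(n_maternal); ti <- n_maternal + seq_len(n_testers)
  # masker: repressive (0) throughout the maternal pool, activating (2) in
  # every tester; dominant-QTL complementing allele fixed in testers
  D[mi, loci$ph_maskerA] <- 0
  D[ti, loci$ph_maskerA] <- 2
  D[ti, loci$ph_dom] <- 2
  # masked loci: testers contribute the null allele so hybrid dosage tracks
  # the maternal allele
  for (l in c("ph_maskedB", paste0("ew_m", 1:6))) D[ti, loci[[l]]] <- 0
  parents$dosages <- D

  design <- enumerate_crosses(maternal_ids, tester_ids)
  f1 <- infer_f1_genotypes(parents, design)
  f1 <- impute_f1_missing(f1, design)

  dom <- function(d) as.numeric(!is.na(d) & d > 0)
  fill0 <- function(d) ifelse(is.na(d), 0, d)
  gv_parent <- function(rows) {
    d <- function(l) fill0(D[rows, loci[[l]]])
    act <- dom(D[rows, loci$ph_maskerA])  # activating allele present?
    list(
      DTT = 2.0 * d("dtt1") + 1.5 * d("dtt2") + 1.0 * d("dtt3"),
      PH = 12 * dom(D[rows, loci$ph_dom]) + 8 * act * d("ph_maskedB") / 2,
      EW = 1.2 * d("ew_add") +
        act * (1.5 * d("ew_m1") + 1.5 * d("ew_m2") + 1.2 * d("ew_m3") +
                 1.2 * d("ew_m4") + 1.0 * d("ew_m5") + 1.0 * d("ew_m6")))
  }
  gv_hybrid <- function() {
    Dh <- f1$dosages
    d <- function(l) fill0(Dh[, loci[[l]]])
    act <- dom(Dh[, loci$ph_maskerA])
    list(
      DTT = 2.0 * d("dtt1") + 1.5 * d("dtt2") + 1.0 * d("dtt3"),
      PH = 12 * dom(Dh[, loci$ph_dom]) + 8 * act * d("ph_maskedB"),
      EW = 1.2 * d("ew_add") +
        act * (1.5 * d("ew_m1") + 1.5 * d("ew_m2") + 1.2 * d("ew_m3") +
                 1.2 * d("ew_m4") + 1.0 * d("ew_m5") + 1.0 * d("ew_m6")))
  }
  intercepts <- c(DTT = 70, PH = 180, EW = 150)
  poly_sd <- c(DTT = 0.8, PH = 3.0, EW = 2.5)
  resid_sd <- c(DTT = 1.2, PH = 6.0, EW = 5.0)

  env_table <- expand.grid(location = sprintf("loc%d", seq_len(n_locations)),
                           year = 2014L + seq_len(n_years) - 1L,
                           stringsAsFactors = FALSE)
  loc_eff <- stats::setNames(stats::rnorm(n_locations, sd = 1),
                             unique(env_table$location))
  year_eff <- stats::setNames(stats::rnorm(n_years, sd = 0.5),
                              unique(env_table$year))

  make_pheno <- function(ids, gvals) {
    traits <- names(gvals)
    out <- list()
    for (tr in traits) {
      g <- intercepts[tr] + gvals[[tr]] +
        stats::rnorm(length(ids), sd = poly_sd[tr])
      for (k in seq_len(nrow(env_table))) {
        out[[length(out) + 1L]] <- data.frame(
          sample = ids, trait = tr,
          location = env_table$location[k], year = env_table$year[k],
          value = g + loc_eff[env_table$location[k]] +
            year_eff[as.character(env_table$year[k])] +
            stats::rnorm(length(ids), sd = resid_sd[tr]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  pheno_parents <- make_pheno(rownames(D), gv_parent(seq_len(n_par)))
  pheno_f1 <- make_pheno(design$crosses$cross, gv_hybrid())

  v <- parents$variants
  truth <- data.frame(
    name = names(loci),
    id = v$id[unlist(loci)], chrom = v$chrom[unlist(loci)],
    pos = v$pos[unlist(loci)],
    trait = c("DTT", "DTT", "DTT", "PH", "PH", "PH", "EW",
              rep("EW", 6)),
    role = c(rep("additive", 3), "dominant", "masker", "masked",
             "additive", rep("masked", 6)),
    expected_class = c(rep("additive", 3), "dominant", NA, "epistatic",
                       "additive", rep("epistatic", 6)),
    stringsAsFactors = FALSE)

  structure(list(parents = parents, maternal_ids = maternal_ids,
                 tester_ids = tester_ids, design = design, f1 = f1,
                 pheno_parents = pheno_parents, pheno_f1 = pheno_f1,
                 truth = truth, traits = c("DTT", "PH", "EW"),
                 seed = seed),
            class = "nc2_study")
}

#' @export
print.nc2_study <- function(x, ...) {
  cat(sprintf("synthetic NC-II study: %d maternal x %d testers, %d variants, traits %s\n",
              length(x$maternal_ids), length(x$tester_ids),
              ncol(x$parents$dosages), paste(x$traits, collapse = "/")))
  invisible(x)
}

#' Run the core discovery pipeline on a study bundle
#'
#' Convenience driver used by the package's end-to-end checks: computes line
#' BLUPs for parents and hybrids, derives MPH, runs the GWAS battery
#' (maternal scan plus per-tester F1 and MPH scans) for the requested traits,
#' calls QTLs per scan, and classifies the merged map by detection pattern.
#'
#' @param study A [gen_full_study()] bundle.
#' @param traits Traits to process (default: just `PH`, the heterosis
#'   showcase trait).
#' @param with_kinship Use mixed-model scans (default) or plain regression.
#' @param cfg An [hf_config()].
#' @return List with `blups`, `gwas` (the battery), `qtls` (per scan),
#'   `map` (classified merged map per trait).
#' @export
run_study_pipeline <- function(study, traits = "PH", with_kinship = TRUE,
                               cfg = hf_config()) {
  par_blup <- do.call(rbind, lapply(traits, function(tr) {
    fit_line_blup(study$pheno_parents, tr)
  }))
  f1_blup <- do.call(rbind, lapply(traits, function(tr) {
    fit_line_blup(study$pheno_f1, tr)
  }))
  cr <- study$design$crosses
  # wide phenotype tables
  mat_wide <- data.frame(sample = study$maternal_ids, stringsAsFactors = FALSE)
  f1_wide <- data.frame(cross = cr$cross, stringsAsFactors = FALSE)
  for (tr in traits) {
    pb <- par_blup[par_blup$trait == tr, ]
    fb <- f1_blup[f1_blup$trait == tr, ]
    mat_wide[[tr]] <- pb$blup[match(study$maternal_ids, pb$sample)]
    yh <- fb$blup[match(cr$cross, fb$sample)]
    ym <- pb$blup[match(cr$maternal, pb$sample)]
    yp <- pb$blup[match(cr$paternal, pb$sample)]
    f1_wide[[tr]] <- yh
    f1_wide[[paste0("MPH.", tr)]] <- compute_mph(yh, ym, yp)
  }
  battery <- run_gwas_battery(
    maternal_gm = study$parents[study$maternal_ids, ],
    maternal_pheno = mat_wide,
    f1_gm = study$f1, f1_pheno = f1_wide, design = study$design,
    traits = traits, mph_traits = paste0("MPH.", traits),
    with_kinship = with_kinship)

  qtls <- lapply(names(battery), function(key) {
    pop <- attr(battery[[key]], "population")
    ld <- if (pop == "maternal") study$parents[study$maternal_ids, ]
          else study$f1[cr$cross[cr$paternal == pop], ]
    call_qtls(battery[[key]], ld, cfg)
  })
  names(qtls) <- names(battery)

  maps <- list()
  for (tr in traits) {
    pick <- function(suffix) {
      keys <- names(qtls)[vapply(qtls, function(q) nrow(q) >= 0, logical(1))]
      keys[endsWith(keys, suffix)]
    }
    m_keys <- paste0("maternal:", tr)
    f_keys <- names(qtls)[grepl(paste0(":", tr, "$"), names(qtls)) &
                            !startsWith(names(qtls), "maternal")]
    h_keys <- names(qtls)[grepl(paste0(":MPH\\.", tr, "$"), names(qtls))]
    maps[[tr]] <- classify_merged_map(
      qtls[intersect(m_keys, names(qtls))],
      qtls[f_keys], qtls[h_keys])
  }
  list(blups = list(parents = par_blup, f1 = f1_blup),
       gwas = battery, qtls = qtls, map = maps)
}
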