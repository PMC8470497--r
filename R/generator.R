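## Random synthetic cohort generator.
##
## Draws cohorts with the statistical structure the classifier assumes:
## subgroup-defining drivers planted per template, background alterations
## drawn per the reference per-subgroup frequencies under the documented
## exclusivity constraints, overexpression folds from range-truncated
## log-normals fitted to the reported subgroup means, exponential survival
## with configured medians and independent censoring.

#' Generator configuration
#'
#' The defaults are the study conditions being emulated: subgroup sizes and
#' alteration frequencies of the reference profile, the reported fold
#' distributions (EGFR-amplified mean 26, range 4.5-72; PDGFRA mean 16.8,
#' range 4.9-25.7; MET-amplified above 40-fold), the reported per-subgroup
#' survival medians with 10 percent independent censoring, and a mild
#' negative TP53/CDKN2A co-occurrence odds ratio.
#'
#' @param seed integer seed (drives all sampling).
#' @param subgroup_sizes named vector of cases per subgroup (the sequenced
#'   subgroups of [gbm_subgroup_sizes()] by default).
#' @param frequencies percent matrix, see [gbm_reference_frequencies()].
#' @param survival_medians months, see [gbm_survival_medians()].
#' @param censor_rate independent censoring probability, default 0.1.
#' @param egfr_fold,pdgfra_fold list(mean, sem, n, range) of the amplified
#'   fold distributions (SEM is converted to SD via sqrt(n)).
#' @param met_min_fold minimum fold of MET-amplified cases, default 40.
#' @param tp53_cdkn2a_or odds ratio of TP53 mutation given CDKN2A loss
#'   (inferred anti-correlation knob; not applied in NF1/IDH), default 0.3.
#' @param expression_rate fraction of cases with transcriptome data,
#'   default 1 (partial transcriptome coverage, and the genomic-only
#'   classification fallback it requires, is a deterministic-fixture
#'   feature; Multi-RTK cases always have expression regardless, since
#'   their assignment requires known fold-changes).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             subgroup_sizes = gbm_subgroup_sizes()[GBM_SUBGROUP_COLS],
                             frequencies = gbm_reference_frequencies(),
                             survival_medians = gbm_survival_medians(),
                             censor_rate = 0.1,
                             egfr_fold = list(mean = 26, sem = 3.7, n = 33,
                                              range = c(4.5, 72)),
                             pdgfra_fold = list(mean = 16.8, sem = 3, n = 7,
                                                range = c(4.9, 25.7)),
                             met_min_fold = 40,
                             tp53_cdkn2a_or = 0.3,
                             expression_rate = 1) {
  cfg <- list(seed = as.integer(seed), subgroup_sizes = subgroup_sizes,
              frequencies = frequencies,
              survival_medians = survival_medians,
              censor_rate = censor_rate, egfr_fold = egfr_fold,
              pdgfra_fold = pdgfra_fold, met_min_fold = met_min_fold,
              tp53_cdkn2a_or = tp53_cdkn2a_or,
              expression_rate = expression_rate)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  f <- cfg$frequencies
  if (any(f < 0 | f > 100)) stop("frequencies must be in [0, 100]")
  if (any(cfg$subgroup_sizes < 0)) stop("subgroup sizes must be >= 0")
  if (any(cfg$survival_medians <= 0)) stop("survival medians must be > 0")
  ## exclusive G1-phase categories must be feasible per column
  g1 <- colSums(f[c("CDKN2A_loss", "CDK4_amp", "RB1"), , drop = FALSE])
  if (any(g1 > 100))
    stop("infeasible constraints: exclusive G1-phase frequencies sum to >100% in ",
         paste(colnames(f)[g1 > 100], collapse = ", "))
  ## composites must dominate their members
  comp <- list(PI3K_mTOR = c("PTEN", "PIK3CA", "PIK3R1"),
               TP53_path = c("TP53", "MDM2_amp", "MDM4_amp", "RPL5", "PPM1D"),
               DDR_path = c("ATM", "BRCA2", "MMR"))
  for (cname in names(comp)) {
    mx <- apply(f[comp[[cname]], , drop = FALSE], 2, max)
    if (any(f[cname, ] < mx - 1e-9))
      stop("infeasible constraints: ", cname,
           " below its member frequency in ",
           paste(colnames(f)[f[cname, ] < mx], collapse = ", "))
  }
  invisible(cfg)
}

## Event-count sampler: stochastic rounding of the expected count. Each
## case's marginal probability equals the configured frequency and the
## across-seed mean count is exactly n * pct / 100, with sub-binomial
## (finite-population style) variance, so seed-averaged frequency-recovery
## audits are sharp even for the smallest subgroups.
rcount <- function(n, pct) {
  x <- n * pct / 100
  as.integer(floor(x) + (stats::runif(1) < x - floor(x)))
}

## Composite count from sampled member counts: the overlap between members
## (and any filler excess) is fixed at its reference value, so the
## composite inherits the members' noise without bias.
comp_count <- function(n, pcomp, km, km_det, filler_ok = FALSE) {
  s_det <- sum(km_det)
  kc_det <- round_half_up(pcomp * n / 100)
  if (filler_ok && kc_det > s_det)   # filler genes absorb the shortfall
    return(min(max(rcount(n, pcomp), if (length(km)) max(km) else 0L), n))
  overlap <- max(0, s_det - kc_det)
  kc <- sum(km) - overlap
  min(max(kc, if (length(km)) max(km) else 0L), n)
}

## range-truncated log-normal sampler matched to a mean and SD
rlnorm_trunc <- function(n, mean, sd, range) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  x <- stats::rlnorm(n, meanlog, sdlog)
  pmin(pmax(x, range[1]), range[2])
}

#' Generate a random synthetic cohort
#'
#' @param config a [generator_config()].
#' @return a `gbm_cohort` with a `truth` attribute (intended labels; written
#'   as `truth.tsv` by [write_cohort()], never read by the classifier).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  freq <- config$frequencies
  sizes <- config$subgroup_sizes

  variants <- list(); cn <- list(); fusions <- list(); clinical <- list()
  folds <- list(); truth <- list()
  addv <- function(id, gene, kind, path = "pathogenic", activating = FALSE,
                   germline = FALSE, hgvs = ".") {
    variants[[length(variants) + 1]] <<- data.frame(
      case_id = id, gene = gene, kind = kind, pathogenicity = path,
      activating = activating, germline = germline, hgvs = hgvs,
      secondary_focus = FALSE, stringsAsFactors = FALSE)
  }
  addcn <- function(id, gene, copy_number, loh = FALSE) {
    cn[[length(cn) + 1]] <<- data.frame(case_id = id, gene = gene,
                                        copy_number = copy_number, loh = loh,
                                        stringsAsFactors = FALSE)
  }
  addfu <- function(id, g5, g3, frame = "in_frame", path = "pathogenic") {
    fusions[[length(fusions) + 1]] <<- data.frame(
      case_id = id, gene5 = g5, gene3 = g3, frame = frame,
      pathogenicity = path, stringsAsFactors = FALSE)
  }
  label_of <- c(EGFR_amp = "G1_EGFR_amp", EGFR_mut = "G1_EGFR_mut",
                PDGFRA = "G5_PDGFRA", MultiRTK = "G6_MultiRTK",
                FGFR3 = "G2_FGFR3", NF1 = "G3_NF1", RAF = "G4_RAF",
                Other = "G7_Other", IDH = "IDH")
  rb1_exception_pool <- character()

  for (grp in names(sizes)) {
    n <- sizes[[grp]]
    if (n == 0) next
    ids <- sprintf("S-%s-%03d", grp, seq_len(n))
    has_expr <- if (grp == "MultiRTK") rep(TRUE, n)
                else stats::runif(n) < config$expression_rate
    for (i in which(has_expr))
      folds[[ids[i]]] <- stats::setNames(
        stats::rlnorm(length(FIXTURE_EXPR_GENES), 0, 0.2),
        FIXTURE_EXPR_GENES)

    pct <- function(feature) freq[feature, grp]
    pick <- function(k) sample.int(n)[seq_len(k)]

    ## G1 phase: mutually exclusive category assignment
    kg1 <- c(rcount(n, pct("CDKN2A_loss")), rcount(n, pct("CDK4_amp")),
             rcount(n, pct("RB1")))
    if (sum(kg1) > n)
      stop("infeasible constraints: G1-phase counts exceed subgroup size in ",
           grp)
    perm <- sample.int(n)
    g1cat <- rep(4L, n)
    g1cat[perm[seq_len(kg1[1])]] <- 1L
    if (kg1[2] > 0) g1cat[perm[kg1[1] + seq_len(kg1[2])]] <- 2L
    if (kg1[3] > 0) g1cat[perm[kg1[1] + kg1[2] + seq_len(kg1[3])]] <- 3L
    for (i in seq_len(n)) {
      if (g1cat[i] == 1) { addcn(ids[i], "CDKN2A", 0)
                           addcn(ids[i], "CDKN2B", 0) }
      if (g1cat[i] == 2) addcn(ids[i], "CDK4", 15 + stats::rpois(1, 10))
      if (g1cat[i] == 3) addv(ids[i], "RB1", "truncating")
    }
    if (grp == "EGFR_amp")
      rb1_exception_pool <- ids[g1cat == 1]

    ## PI3K/mTOR: members then overlap to the composite target
    kdet <- function(feature) round_half_up(freq[feature, grp] * n / 100)
    km <- c(PTEN = rcount(n, pct("PTEN")),
            PIK3CA = rcount(n, pct("PIK3CA")),
            PIK3R1 = rcount(n, pct("PIK3R1")))
    kc <- comp_count(n, freq["PI3K_mTOR", grp], km,
                     c(kdet("PTEN"), kdet("PIK3CA"), kdet("PIK3R1")),
                     filler_ok = TRUE)
    lay <- lay_members(sample.int(n)[seq_len(kc)], km, filler = "TSC2")
    for (g in names(lay)) for (i in lay[[g]]) addv(ids[i], g, "truncating")

    ## TP53 pathway, with the CDKN2A anti-correlation knob steering which
    ## cases carry TP53
    km <- c(MDM2 = rcount(n, pct("MDM2_amp")),
            MDM4 = rcount(n, pct("MDM4_amp")),
            RPL5 = rcount(n, pct("RPL5")),
            PPM1D = rcount(n, pct("PPM1D")),
            TP53 = rcount(n, pct("TP53")))
    kc <- comp_count(n, freq["TP53_path", grp], km,
                     c(kdet("MDM2_amp"), kdet("MDM4_amp"), kdet("RPL5"),
                       kdet("PPM1D"), kdet("TP53")))
    ord <- if (grp %in% c("NF1", "IDH")) sample.int(n)
           else order(ifelse(g1cat == 1, config$tp53_cdkn2a_or, 1) *
                        stats::runif(n), decreasing = TRUE)
    lay <- lay_members(ord[seq_len(kc)], km)
    for (g in names(lay)) for (i in lay[[g]]) {
      if (g %in% c("MDM2", "MDM4")) addcn(ids[i], g, 14)
      else addv(ids[i], g, "missense")
    }

    ## DNA-damage response
    km <- c(ATM = rcount(n, pct("ATM")),
            BRCA2 = rcount(n, pct("BRCA2")),
            MSH6 = rcount(n, pct("MMR")))
    kc <- comp_count(n, freq["DDR_path", grp], km,
                     c(kdet("ATM"), kdet("BRCA2"), kdet("MMR")))
    lay <- lay_members(sample.int(n)[seq_len(kc)], km)
    for (g in names(lay)) for (i in lay[[g]]) addv(ids[i], g, "truncating")

    ## independent single-feature rows
    for (i in pick(rcount(n, pct("STAG2")))) addv(ids[i], "STAG2", "truncating")
    for (i in pick(rcount(n, pct("SWI_SNF"))))
      addv(ids[i], "ARID1A", "truncating")
    for (i in pick(rcount(n, pct("ChRm")))) addv(ids[i], "DNMT3A", "missense")

    ## TERT promoter; expression carries the overexpression arm
    tert_mut <- rep(FALSE, n)
    tert_mut[pick(rcount(n, pct("TERT")))] <- TRUE
    for (i in which(tert_mut)) addv(ids[i], "TERT", "promoter_mutation")
    for (i in which(has_expr))
      folds[[ids[i]]]["TERT"] <- if (tert_mut[i])
        stats::rlnorm(1, log(8), 0.3) else stats::rlnorm(1, log(1), 0.2)

    ## MGMT methylation value
    mg <- stats::runif(n, 0, 4.9)
    kmg <- rcount(n, pct("MGMT_methyl"))
    mg[pick(kmg)] <- stats::runif(kmg, 5, 30)

    ## subgroup-defining drivers
    for (i in seq_len(n)) {
      id <- ids[i]
      set_fold <- function(gene, value) {
        if (has_expr[i]) folds[[id]][gene] <<- value
      }
      if (grp == "EGFR_amp") {
        addcn(id, "EGFR", stats::runif(1, 7, 60))
        fl <- rlnorm_trunc(1, config$egfr_fold$mean,
                           config$egfr_fold$sem * sqrt(config$egfr_fold$n),
                           config$egfr_fold$range)
        set_fold("EGFR", fl)
        if ((has_expr[i] && fl < 5) || stats::runif(1) < 0.7)
          addv(id, "EGFR", "splice_variant", activating = TRUE, hgvs = "vIII")
      } else if (grp == "EGFR_mut") {
        addv(id, "EGFR", "missense", activating = TRUE, hgvs = "p.C620Y")
        set_fold("EGFR", stats::rlnorm(1, log(2), 0.3))
      } else if (grp == "PDGFRA") {
        amp <- i <= round(0.857 * n)
        fl <- rlnorm_trunc(1, config$pdgfra_fold$mean,
                           config$pdgfra_fold$sem * sqrt(config$pdgfra_fold$n),
                           config$pdgfra_fold$range)
        set_fold("PDGFRA", max(fl, if (amp) 0 else 6))
        if (amp) {
          addcn(id, "PDGFRA", stats::runif(1, 7, 50))
          if ((has_expr[i] && fl < 5) || stats::runif(1) < 0.4)
            addv(id, "PDGFRA", "missense", activating = TRUE,
                 hgvs = "p.Y288C")
        } else addv(id, "PDGFRA", "missense", activating = TRUE,
                    hgvs = "p.Y288C")
      } else if (grp == "MultiRTK") {
        tmpl <- 1 + (i - 1) %% 4
        if (tmpl == 1) {          # PDGFRA amplified without overexpression
          addcn(id, "PDGFRA", stats::runif(1, 7, 20))
          set_fold("PDGFRA", min(stats::rlnorm(1, log(2), 0.3), 4.5))
        } else if (tmpl == 2) {   # MET amplified, very high fold
          addcn(id, "MET", stats::runif(1, 7, 20))
          set_fold("MET", config$met_min_fold * stats::runif(1, 1, 1.5))
        } else if (tmpl == 3) {   # lone non-canonical RTK fusion
          addfu(id, "LMNA", "NTRK1")
        } else {                  # two concurrent RTK drivers
          addcn(id, "EGFR", stats::runif(1, 7, 20))
          set_fold("EGFR", stats::runif(1, 6, 20))
          addcn(id, "MET", stats::runif(1, 3, 6))
          set_fold("MET", stats::runif(1, 11, 30))
        }
      } else if (grp == "FGFR3") {
        if (stats::runif(1) < 0.8) addfu(id, "FGFR3", "TACC3")
        else addv(id, "FGFR3", "missense", activating = TRUE,
                  hgvs = "p.S249C")
        set_fold("FGFR3", stats::runif(1, 10, 35))
      } else if (grp == "NF1") {
        addv(id, "NF1", "truncating")
        if (stats::runif(1) < 0.5) addcn(id, "NF1", 1, loh = TRUE)
        else addv(id, "NF1", "frameshift")
      } else if (grp == "RAF") {
        if (stats::runif(1) < 0.75)
          addv(id, "BRAF", "missense", activating = TRUE, hgvs = "p.V600E")
        else addv(id, "RAF1", "missense", activating = TRUE,
                  hgvs = "p.S257L")
      } else if (grp == "IDH") {
        addv(id, "IDH1", "missense", hgvs = "p.R132H")
      }
      ## "Other": no driver; guaranteed genomic rows via PI3K at 100%
    }

    ## clinical
    med <- config$survival_medians[[grp]]
    rate <- log(2) / med
    t_ev <- stats::rexp(n, rate)
    cr <- config$censor_rate
    t_cs <- if (cr > 0) stats::rexp(n, rate * cr / (1 - cr)) else rep(Inf, n)
    surv <- round(pmin(t_ev, t_cs), 2)
    event <- t_ev <= t_cs
    age_mean <- if (grp == "MultiRTK") 70 else if (grp == "IDH") 42 else 61
    patterns <- fixture_histology[[grp]]
    clinical[[length(clinical) + 1]] <- data.frame(
      case_id = ids,
      age = pmax(19, round(stats::rnorm(n, age_mean, 9))),
      sex = sample(c("M", "F"), n, TRUE,
                   prob = if (grp == "IDH") c(0.05, 0.95) else c(0.61, 0.39)),
      ethnicity = sample(GBM_ETHNICITY, n, TRUE, prob = c(0.78, 0.17, 0.05)),
      location = sample(GBM_LOCATION, n, TRUE,
                        prob = c(0.3, 0.3, 0.17, 0.15, 0.05, 0.03)),
      survival_months = surv, event_observed = event,
      idh1_r132h = if (grp == "IDH") "positive" else "negative",
      h3_k27m = "negative", gfap = "high",
      p53 = 1L, ki67 = 20L,
      histologic_pattern = sample(patterns, n, TRUE),
      mgmt_value = round(mg, 2),
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- data.frame(
      case_id = ids, intended_label = label_of[[grp]],
      stringsAsFactors = FALSE)
  }

  ## the two cohort-wide germline RB1 point-variant exceptions
  if (length(rb1_exception_pool) >= 2)
    for (id in rb1_exception_pool[1:2])
      addv(id, "RB1", "missense", path = "vus", germline = TRUE,
           hgvs = "p.Arg320Cys")

  clinical <- do.call(rbind, clinical)
  genes <- c(FIXTURE_EXPR_GENES, "LOWCOUNT1", "PSEUDO1", "RPS4Y1")
  samples <- names(folds)
  expr <- matrix(300, length(genes), length(samples) + 3,
                 dimnames = list(genes,
                                 c(samples, paste0("control:LGG", 1:3))))
  for (s in samples) expr[FIXTURE_EXPR_GENES, s] <-
    round(folds[[s]][FIXTURE_EXPR_GENES] * 1000)
  expr["LOWCOUNT1", samples] <- 499
  expr["PSEUDO1", samples] <- 2000
  expr["RPS4Y1", samples] <- 3000
  expr[FIXTURE_EXPR_GENES, paste0("control:LGG", 1:3)] <-
    rep(c(950, 1000, 1050), each = length(FIXTURE_EXPR_GENES))
  annotation <- data.frame(
    gene = genes, is_pseudogene = genes == "PSEUDO1",
    chromosome = ifelse(genes == "RPS4Y1", "Y", "autosome"),
    stringsAsFactors = FALSE)
  co <- new_cohort(clinical, do.call(rbind, variants), do.call(rbind, cn),
                   do.call(rbind, fusions), expr, annotation,
                   name = sprintf("synthetic_seed%d", config$seed))
  attr(co, "truth") <- do.call(rbind, truth)
  co
}

#' Simulate subgroup survival records
#'
#' Exponential survival with the given median and independent exponential
#' censoring calibrated to the configured censoring fraction (the
#' generator's survival model, exposed for calibration studies).
#'
#' @param n number of cases.
#' @param median_months exponential median.
#' @param censor_rate expected censored fraction, default 0.1.
#' @param seed optional integer seed.
#' @return data.frame with `time` and `event`.
#' @export
simulate_survival <- function(n, median_months, censor_rate = 0.1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- log(2) / median_months
  t_ev <- stats::rexp(n, rate)
  t_cs <- if (censor_rate > 0)
    stats::rexp(n, rate * censor_rate / (1 - censor_rate)) else rep(Inf, n)
  data.frame(time = pmin(t_ev, t_cs), event = t_ev <= t_cs)
}
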