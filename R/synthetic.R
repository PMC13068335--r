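#' @keywords internal
#' Approximate SD of log2(count + 0.5) for NB(mu, size) by the delta method;
#' used to convert a standardized effect into a mean fold change.
nb_log2_sd <- function(mu, size) {
  sqrt(mu + mu^2 / size) / ((mu + 0.5) * log(2))
}

#' The five late-phase biomarker panels fixture
#'
#' Deterministic synthetic stand-in for the five LAR biomarker panels: sizes
#' 40, 33, 35, 34 and 14 (156 slots in total) with 109 unique symbols. The
#' overlap structure satisfies every printed marginal that can be satisfied
#' jointly: 37 panel-1 genes unique + 3 shared, 10 Trinity-unique genes, 11
#' genes shared by three panels, 9 shared by the isoform and Ensembl panels
#' only. Symbols are synthetic (`LARB001`...).
#'
#' @return Named list of five character vectors: `PanCancer`, `UCSC_genes`,
#'   `UCSC_isoforms`, `Ensembl`, `Trinity`.
#' @export
gen_biomarker_panels <- function() {
  g <- sprintf("LARB%03d", 1:109)
  u_pc  <- g[1:37]     # PanCancer unique
  u_ucsc <- g[38:47]   # UCSC genes unique
  u_iso <- g[48:57]    # UCSC isoforms unique
  u_ens <- g[58:63]    # Ensembl unique
  u_tri <- g[64:73]    # Trinity unique
  p_pc_iso  <- g[74:76]    # PanCancer & isoforms
  p_iso_ens <- g[77:85]    # isoforms & Ensembl
  p_ucsc_tri <- g[86:89]   # UCSC & Trinity
  p_ucsc_ens <- g[90:98]   # UCSC & Ensembl
  t_uie <- g[99:109]       # UCSC & isoforms & Ensembl
  list(
    PanCancer = c(u_pc, p_pc_iso),
    UCSC_genes = c(u_ucsc, p_ucsc_tri, p_ucsc_ens, t_uie),
    UCSC_isoforms = c(u_iso, p_pc_iso, p_iso_ens, t_uie),
    Ensembl = c(u_ens, p_iso_ens, p_ucsc_ens, t_uie),
    Trinity = c(u_tri, p_ucsc_tri)
  )
}

#' Generate a NanoString-like allergen-challenge cohort
#'
#' Emulates the discovery cohort: negative-binomial counts for `n_genes`
#' panel genes (including housekeeping genes and appended negative-control
#' probes), with `n_informative` genes shifted upward in dual responders by
#' `effect` standardized (log2) units; FEV1 trajectories in which every
#' subject shows an early-phase fall of at least 20% and dual responders show
#' the late-phase fall (or the borderline 10-15% fall rescued by an
#' allergen-induced PC20 shift >= 2); and PC20 pairs consistent with each
#' subject's class.
#'
#' @param n_er,n_dr Subjects per class, defaults 15 and 20.
#' @param n_genes Panel genes, default 770 (includes housekeeping).
#' @param n_housekeeping Housekeeping genes, default 40.
#' @param n_negative_controls Negative-control probes appended, default 8.
#' @param n_informative Planted discriminative genes, default 25.
#' @param effect Standardized log2 effect size in DRs, default 1.5.
#' @param frac_low Fraction of non-housekeeping genes simulated near
#'   background (removed by abundance filtering), default 0.17, chosen so
#'   that roughly 600 of the 770 panel genes survive housekeeping and
#'   abundance filtering, the discovery-cohort outcome.
#' @param borderline_frac Fraction of DRs classified via the AIS rescue rule,
#'   default 0.1 (2 of 20).
#' @param seed Integer seed.
#' @return A list: `expression` ([expression_matrix()], counts), `samples`
#'   ([sample_table()]), `genes` ([gene_table()]), `spirometry` (long
#'   data.frame for [classify_responders()]), `truth` (planted classes,
#'   informative genes and effects).
#' @export
gen_challenge_cohort <- function(n_er = 15, n_dr = 20, n_genes = 770,
                                 n_housekeeping = 40, n_negative_controls = 8,
                                 n_informative = 25, effect = 1.5,
                                 frac_low = 0.17, borderline_frac = 0.1,
                                 seed = 1) {
  if (n_informative > n_genes - n_housekeeping)
    stop("n_informative exceeds the number of non-housekeeping genes")
  withr::with_seed(as.integer(seed), {
    n <- n_er + n_dr
    subj <- sprintf("S%02d", seq_len(n))
    cls <- c(rep("ER", n_er), rep("DR", n_dr))
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    hk <- sample(genes, n_housekeeping)
    negs <- sprintf("NEG%02d", seq_len(n_negative_controls))
    non_hk <- setdiff(genes, hk)
    low <- sample(non_hk, round(frac_low * length(non_hk)))
    expressed <- setdiff(non_hk, low)
    informative <- sample(expressed, n_informative)

    mu <- stats::setNames(stats::rlnorm(n_genes, meanlog = 4.5, sdlog = 1.0), genes)
    mu[hk] <- stats::rlnorm(n_housekeeping, meanlog = 6, sdlog = 0.4)
    mu[low] <- stats::runif(length(low), 1, 6)
    mu_neg <- stats::setNames(stats::runif(n_negative_controls, 2, 6), negs)
    size <- stats::setNames(rep(10, n_genes), genes)
    size[hk] <- 50

    all_ids <- c(genes, negs)
    counts <- matrix(0, length(all_ids), n, dimnames = list(all_ids, subj))
    fc <- stats::setNames(2^(effect * nb_log2_sd(mu[informative], size[informative])),
                          informative)
    for (j in seq_len(n)) {
      m <- mu
      if (cls[j] == "DR") m[informative] <- m[informative] * fc
      counts[genes, j] <- stats::rnbinom(n_genes, mu = m, size = size)
      counts[negs, j] <- stats::rnbinom(n_negative_controls, mu = mu_neg, size = 20)
    }

    gt <- gene_table(
      symbol = all_ids,
      is_housekeeping = all_ids %in% hk,
      is_negative_control = all_ids %in% negs
    )
    st <- sample_table(
      sample_id = subj, group = cls,
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.3, 0.7)),
      batch = sample(c("Laval", "McMaster", "UBC"), n, replace = TRUE,
                     prob = c(0.57, 0.34, 0.09))
    )

    n_borderline <- round(borderline_frac * n_dr)
    borderline <- c(rep(FALSE, n_er),
                    sample(c(rep(TRUE, n_borderline),
                             rep(FALSE, n_dr - n_borderline))))
    times <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 7)
    spiro <- vector("list", n)
    ais <- numeric(n)
    for (j in seq_len(n)) {
      ear <- -pmax(stats::rnorm(1, 35, 9), 21)
      if (cls[j] == "ER") {
        late <- -stats::runif(1, 2, 9.5)
        ais[j] <- stats::rlnorm(1, log(1.5), 0.5)
      } else if (borderline[j]) {
        late <- -stats::runif(1, 10.5, 14.9)
        ais[j] <- stats::runif(1, 2.1, 6)
      } else {
        late <- -pmax(stats::rnorm(1, 30, 10), 15.5)
        ais[j] <- pmax(stats::rlnorm(1, log(3), 0.5), 0.3)
      }
      recov <- late / 3
      # late-phase nadir at 5 h, or at 7 h for borderline DRs (response still
      # developing at the last measurement)
      traj <- if (cls[j] == "DR" && borderline[j])
        c(0, ear * 0.6, ear, ear * 0.5, recov, recov, late * 0.4, late * 0.6,
          late * 0.85, late)
      else
        c(0, ear * 0.6, ear, ear * 0.5, recov, recov, late * 0.7, late,
          late * 0.8, late * 0.7)
      pc20_pre <- stats::rlnorm(1, log(2), 0.8)
      spiro[[j]] <- data.frame(
        subject_id = subj[j], time_h = times, fev1_pct_change = traj,
        pc20_pre = pc20_pre, pc20_post = pc20_pre / ais[j],
        stringsAsFactors = FALSE
      )
    }
    list(
      expression = expression_matrix(counts, value_kind = "counts"),
      samples = st, genes = gt,
      spirometry = do.call(rbind, spiro),
      truth = list(class = stats::setNames(cls, subj),
                   informative = informative, fold_change = fc,
                   housekeeping = hk, low_abundance = low,
                   borderline = stats::setNames(borderline, subj), ais = ais)
    )
  })
}

#' Default multi-cohort bulk design
#'
#' Dataset skeletons mirroring the structure of the public cohorts used for
#' exacerbation and severity evaluation: a PBMC exacerbation time-series,
#' endobronchial biopsy, induced sputum (two cohorts), BALF, whole blood and
#' bronchial epithelial severity cohorts. Group sizes follow the source
#' cohorts; pass a trimmed design to the generator for quick runs.
#'
#' @return A named list of dataset specifications.
#' @export
default_bulk_design <- function() {
  list(
    pbmc_exacerbation = list(
      sample_type = "blood", groups = c(quiet = 180, exacerbation = 68,
                                        follow_up = 60)),
    biopsy_severity = list(
      sample_type = "airway", groups = c(healthy = 13, moderate = 18, severe = 42)),
    sputum_severity_a = list(
      sample_type = "sputum", groups = c(healthy = 10, moderate = 18, severe = 16)),
    sputum_severity_b = list(
      sample_type = "sputum", groups = c(healthy = 21, moderate = 25, severe = 93)),
    balf_severity = list(
      sample_type = "balf", groups = c(healthy = 12, moderate = 28, severe = 46)),
    blood_severity = list(
      sample_type = "blood", groups = c(healthy = 87, moderate = 77, severe = 334)),
    epithelium_severity = list(
      sample_type = "airway", groups = c(healthy = 16, moderate = 5, severe = 17))
  )
}

#' Y-chromosome marker genes used by the generators
#' @keywords internal
y_marker_genes <- function() c("RPS4Y1", "DDX3Y", "EIF1AY", "KDM5D", "UTY", "USP9Y")

#' Generate multi-dataset bulk cohorts with planted structure
#'
#' Gaussian log-intensity matrices per declared dataset with planted group
#' effects on panel genes, additive per-gene batch shifts, Y-gene elevation in
#' males, and optionally male-only effect genes.
#'
#' @param design Named list of dataset specs (`sample_type`, `groups`: named
#'   group sizes); see [default_bulk_design()].
#' @param panel Character vector of panel genes carrying the group effect
#'   (defaults to the combined biomarker panel fixture).
#' @param n_background Additional null genes, default 400.
#' @param effect Group effect in SD units on panel genes for affected groups,
#'   default 1.
#' @param male_only_genes Number of panel genes whose effect is present in
#'   males only, default 0.
#' @param male_effect Effect size for male-only genes, default 1.5.
#' @param batch_shift SD of the per-gene additive shift applied to the second
#'   half of each dataset's samples (two batches per dataset); 0 disables
#'   batching, default 0.
#' @param y_effect Y-gene elevation in males (SD units), default 5.
#' @param frac_male Probability a sample is male, default 0.5.
#' @param seed Integer seed.
#' @return Named list per dataset: `expression`, `samples`, `genes`, plus a
#'   shared `truth` entry (affected genes, male-only genes, per-dataset sex
#'   and batch assignments).
#' @export
gen_bulk_cohorts <- function(design = default_bulk_design(),
                             panel = unique(unlist(gen_biomarker_panels())),
                             n_background = 400, effect = 1,
                             male_only_genes = 0, male_effect = 1.5,
                             batch_shift = 0, y_effect = 5, frac_male = 0.5,
                             seed = 1) {
  withr::with_seed(as.integer(seed), {
    small <- unlist(lapply(design, function(d) d$groups))
    if (any(small < 5))
      warning("group(s) with fewer than 5 samples; cross-validation may be infeasible")
    ygenes <- y_marker_genes()
    background <- sprintf("BG%04d", seq_len(n_background))
    genes <- unique(c(panel, background, ygenes))
    gt <- gene_table(symbol = genes,
                     chromosome = ifelse(genes %in% ygenes, "Y", NA_character_))
    male_only <- if (male_only_genes > 0) sample(panel, male_only_genes) else character(0)
    sexed_effect_panel <- setdiff(panel, male_only)
    out <- list()
    truth_sex <- list(); truth_batch <- list()
    for (ds in names(design)) {
      spec <- design[[ds]]
      grp <- rep(names(spec$groups), spec$groups)
      n <- length(grp)
      ids <- sprintf("%s_%03d", ds, seq_len(n))
      sex <- sample(c("male", "female"), n, replace = TRUE,
                    prob = c(frac_male, 1 - frac_male))
      mu <- stats::rnorm(length(genes), mean = 7, sd = 1.5)
      vals <- matrix(stats::rnorm(length(genes) * n, mean = mu, sd = 1),
                     length(genes), n, dimnames = list(genes, ids))
      # ordinal group effect: later-declared groups are 'worse'
      lvl <- match(grp, names(spec$groups)) - 1L
      aff <- intersect(sexed_effect_panel, genes)
      vals[aff, ] <- vals[aff, ] +
        effect * matrix(lvl, length(aff), n, byrow = TRUE) /
        max(1, length(spec$groups) - 1)
      if (length(male_only)) {
        mm <- (sex == "male") * lvl / max(1, length(spec$groups) - 1)
        vals[male_only, ] <- vals[male_only, ] +
          male_effect * matrix(mm, length(male_only), n, byrow = TRUE)
      }
      vals[ygenes, sex == "male"] <- vals[ygenes, sex == "male"] + y_effect
      batch <- rep("b1", n)
      if (batch_shift > 0) {
        batch[seq_len(n) %% 2 == 0] <- "b2"  # interleaved: balanced over groups
        delta <- stats::rnorm(length(genes), 0, batch_shift)
        vals[, batch == "b2"] <- vals[, batch == "b2"] + delta
      }
      out[[ds]] <- list(
        expression = expression_matrix(vals, value_kind = "log_intensity"),
        samples = sample_table(sample_id = ids, group = grp, sex = sex,
                               batch = paste(ds, batch, sep = "_")),
        genes = gt
      )
      truth_sex[[ds]] <- stats::setNames(sex, ids)
      truth_batch[[ds]] <- stats::setNames(batch, ids)
    }
    out$truth <- list(affected_genes = sexed_effect_panel,
                      male_only_genes = male_only, effect = effect,
                      sex = truth_sex, batch = truth_batch)
    out
  })
}

#' Generate a pre/post-challenge single-cell biopsy dataset
#'
#' Negative-binomial counts per cell with planted cell-type-restricted
#' up-regulation: in asthma-group cells of the designated cell types, the
#' allergen condition multiplies planted-set gene means by `2^effect`;
#' allergic-control cells are unchanged.
#'
#' @param n_subjects_per_group Subjects per group, default 4.
#' @param cell_types Major cell types, default five biopsy populations.
#' @param subtype_map Optional named list `cell_type -> subtypes` adding a
#'   `subtype` annotation.
#' @param planted_sets Named list (cell type -> gene symbols) of up-regulated
#'   sets; every name must be a known cell type.
#' @param effect Log2 effect, default 1.
#' @param n_genes Total genes (planted genes included), default 300.
#' @param cells_per_stratum Cells per (subject, condition, cell type), default 30.
#' @param size NB dispersion size, default 2.
#' @param seed Integer seed.
#' @return A list: `dataset` ([single_cell_dataset()]) and `truth`.
#' @export
gen_sc_biopsy <- function(n_subjects_per_group = 4,
                          cell_types = c("CD4 T", "CD8 T", "B", "NK", "MNP"),
                          subtype_map = NULL, planted_sets, effect = 1,
                          n_genes = 300, cells_per_stratum = 30, size = 2,
                          seed = 1) {
  unknown <- setdiff(names(planted_sets), cell_types)
  if (length(unknown))
    stop("planted set references unknown cell type(s): ",
         paste(unknown, collapse = ", "))
  withr::with_seed(as.integer(seed), {
    planted_genes <- unique(unlist(planted_sets))
    background <- sprintf("SCG%04d", seq_len(max(0, n_genes - length(planted_genes))))
    genes <- unique(c(planted_genes, background))
    mu <- stats::setNames(stats::rlnorm(length(genes), log(2), 0.8), genes)
    groups <- c(rep("allergic_asthma", n_subjects_per_group),
                rep("allergic_control", n_subjects_per_group))
    subjects <- c(sprintf("AA%d", seq_len(n_subjects_per_group)),
                  sprintf("AC%d", seq_len(n_subjects_per_group)))
    rows <- list(); counts <- list()
    for (i in seq_along(subjects)) {
      for (cond in c("baseline", "allergen")) {
        for (ct in cell_types) {
          m <- mu
          if (groups[i] == "allergic_asthma" && cond == "allergen" &&
              ct %in% names(planted_sets)) {
            g <- planted_sets[[ct]]
            m[g] <- m[g] * 2^effect
          }
          k <- cells_per_stratum
          cm <- matrix(stats::rnbinom(k * length(genes), mu = rep(m, each = k),
                                      size = size), k, length(genes))
          counts[[length(counts) + 1L]] <- cm
          ann <- data.frame(
            cell_id = sprintf("%s_%s_%s_c%02d", subjects[i], cond,
                              gsub(" ", "", ct), seq_len(k)),
            cell_type = ct, sample_id = paste(subjects[i], cond, sep = "_"),
            subject_id = subjects[i], condition = cond, group = groups[i],
            stringsAsFactors = FALSE
          )
          if (!is.null(subtype_map) && ct %in% names(subtype_map))
            ann$subtype <- sample(subtype_map[[ct]], k, replace = TRUE)
          else if (!is.null(subtype_map)) ann$subtype <- ct
          rows[[length(rows) + 1L]] <- ann
        }
      }
    }
    cd <- do.call(rbind, rows)
    mat <- Matrix::Matrix(do.call(rbind, counts), sparse = TRUE)
    ds <- single_cell_dataset(mat, cd, gene_ids = genes)
    list(dataset = ds,
         truth = list(planted_sets = planted_sets, effect = effect,
                      groups = stats::setNames(groups, subjects)))
  })
}

#' Generate a PBMC drug-perturbation screen
#'
#' Emulates a compound screen: `n_compounds` small molecules plus two positive
#' controls and a DMSO vehicle, across donors and cell types. Planted
#' reversers shift the disease up-set genes down and the down-set genes up by
#' `effect` log2 units in every cell type; mimics do the opposite; the
#' remaining compounds perturb a few random non-target genes.
#'
#' @param n_compounds Number of library compounds, default 144.
#' @param n_donors Donors, default 3.
#' @param cell_types Screen cell types, default five PBMC populations.
#' @param reverser_ids,mimic_ids Compound ids (within the library) planted as
#'   reversers / mimics; must not overlap. `NULL` (default) plants one of
#'   each at fixed library positions.
#' @param target_sets List with `up` and `down`: named per-cell-type gene
#'   sets (the disease signature to reverse). The same genes are used in
#'   every cell type's perturbation.
#' @param effect Log2 shift magnitude, default 1.
#' @param n_genes Total genes, default 200 (target genes included).
#' @param cells_per_stratum Cells per (compound, donor, cell type), default 8.
#' @param off_target_genes Genes perturbed by non-planted compounds, default 10.
#' @param size NB dispersion, default 2.
#' @param seed Integer seed.
#' @return A list: `dataset`, `truth` (reversers, mimics, positive controls,
#'   vehicle label).
#' @export
gen_perturbation <- function(n_compounds = 144, n_donors = 3,
                             cell_types = c("CD4 T", "CD8 T", "Myeloid", "B", "NK"),
                             reverser_ids = NULL, mimic_ids = NULL,
                             target_sets, effect = 1, n_genes = 200,
                             cells_per_stratum = 8, off_target_genes = 10,
                             size = 2, seed = 1) {
  compounds <- sprintf("DRUG%03d", seq_len(n_compounds))
  if (is.null(reverser_ids)) reverser_ids <- compounds[min(42L, n_compounds)]
  if (is.null(mimic_ids))
    mimic_ids <- setdiff(compounds, reverser_ids)[min(106L, n_compounds - 1L)]
  if (length(intersect(reverser_ids, mimic_ids)))
    stop("reverser and mimic ids overlap")
  bad <- setdiff(c(reverser_ids, mimic_ids), compounds)
  if (length(bad)) stop("unknown compound id(s): ", paste(bad, collapse = ", "))
  pos_controls <- c("dabrafenib_analog", "belinostat_analog")
  vehicle <- "DMSO"
  withr::with_seed(as.integer(seed), {
    up_genes <- unique(unlist(target_sets$up))
    down_genes <- unique(unlist(target_sets$down))
    target <- union(up_genes, down_genes)
    background <- sprintf("PBG%04d", seq_len(max(0, n_genes - length(target))))
    genes <- unique(c(target, background))
    mu <- stats::setNames(stats::rlnorm(length(genes), log(3), 0.7), genes)
    all_compounds <- c(vehicle, compounds, pos_controls)
    # fixed per-compound off-target perturbations, shared across donors/cell types
    off <- lapply(all_compounds, function(cmp) {
      if (cmp %in% c(vehicle, reverser_ids, mimic_ids)) return(NULL)
      g <- sample(setdiff(genes, target), off_target_genes)
      stats::setNames(sample(c(-1, 1), off_target_genes, TRUE) * effect / 2, g)
    })
    names(off) <- all_compounds
    rows <- list(); counts <- list()
    for (donor in sprintf("DONOR%d", seq_len(n_donors))) {
      for (cmp in all_compounds) {
        m <- mu
        if (cmp %in% reverser_ids) {
          m[up_genes] <- m[up_genes] * 2^(-effect)
          m[down_genes] <- m[down_genes] * 2^(effect)
        } else if (cmp %in% mimic_ids) {
          m[up_genes] <- m[up_genes] * 2^(effect)
          m[down_genes] <- m[down_genes] * 2^(-effect)
        } else if (!is.null(off[[cmp]])) {
          g <- names(off[[cmp]])
          m[g] <- m[g] * 2^(off[[cmp]])
        }
        for (ct in cell_types) {
          k <- cells_per_stratum
          cm <- matrix(stats::rnbinom(k * length(genes), mu = rep(m, each = k),
                                      size = size), k, length(genes))
          counts[[length(counts) + 1L]] <- cm
          rows[[length(rows) + 1L]] <- data.frame(
            cell_id = sprintf("%s_%s_%s_c%02d", donor, cmp, gsub(" ", "", ct),
                              seq_len(k)),
            cell_type = ct, compound = cmp, donor = donor,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    cd <- do.call(rbind, rows)
    mat <- Matrix::Matrix(do.call(rbind, counts), sparse = TRUE)
    ds <- single_cell_dataset(mat, cd, gene_ids = genes)
    list(dataset = ds,
         truth = list(reversers = reverser_ids, mimics = mimic_ids,
                      positive_controls = pos_controls, vehicle = vehicle,
                      target_sets = target_sets, effect = effect))
  })
}
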