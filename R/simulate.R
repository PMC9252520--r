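#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every parameter of the synthetic study: a tumor cohort with `k`
#' planted expression subtypes and matched normals, an implanted up/down
#' disease signature, a drug perturbation library in which a known subset
#' of drugs reverses that signature (more strongly at high dose / long
#' duration), and dose-response AUCs monotonically linked to reversal
#' strength plus noise.
#'
#' @param seed master seed; every generator draw flows from it.
#' @param n_genes gene universe size.
#' @param k number of planted subtypes.
#' @param samples_per_subtype tumor samples per subtype.
#' @param n_normals normal pool size.
#' @param shift between-subtype log2 mean shift of each subtype's marker
#'   block.
#' @param block_size genes per subtype marker block.
#' @param noise_sd within-sample log2 noise SD.
#' @param sig_size planted signature genes per direction.
#' @param sig_effect planted log2 fold change of signature genes (tumor vs
#'   normal); 2 = 4-fold.
#' @param sig_activity_range range of the per-tumor disease-signature
#'   activity, drawn uniformly; a tumor's signature shift is
#'   `activity * sig_effect` and the held-out patient has activity 1.
#'   A range below `c(1, 1)` makes signature strength heterogeneous across
#'   the cohort, so subgroups picked by similarity to the patient carry the
#'   signature more strongly than random subgroups — the property the
#'   permutation-null validation probes.
#' @param alpha_range range of the normal-contamination fraction mixed into
#'   each tumor (c(0, 0) = none).
#' @param n_drugs,n_reversers library size and number of true reversers.
#' @param doses,times dose (uM) / duration (h) grid; must include the
#'   10 uM / 24 h reference.
#' @param pert_effect score shift applied to signature genes in a
#'   reverser's ranking at the reference condition.
#' @param auc_intercept,auc_slope,auc_noise_sd linear link from planted
#'   reversal strength to AUC.
#' @param n_patients simulated patients with response labels.
#' @param label_noise_sd SD of the noise added to a patient's score before
#'   thresholding into responder / non-responder.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, n_genes = 2000L, k = 3L,
                            samples_per_subtype = 30L, n_normals = 30L,
                            shift = 2, block_size = 100L, noise_sd = 0.5,
                            sig_size = 100L, sig_effect = 2,
                            sig_activity_range = c(0.2, 1),
                            alpha_range = c(0, 0),
                            n_drugs = 20L, n_reversers = 5L,
                            doses = c(1, 10), times = c(6, 24),
                            pert_effect = 3,
                            auc_intercept = 0.7, auc_slope = 0.5,
                            auc_noise_sd = 0.05,
                            n_patients = 40L, label_noise_sd = 1.3) {
  cfg <- list(seed = seed, n_genes = n_genes, k = k,
              samples_per_subtype = samples_per_subtype,
              n_normals = n_normals, shift = shift, block_size = block_size,
              noise_sd = noise_sd, sig_size = sig_size,
              sig_effect = sig_effect,
              sig_activity_range = sig_activity_range,
              alpha_range = alpha_range,
              n_drugs = n_drugs, n_reversers = n_reversers,
              doses = doses, times = times, pert_effect = pert_effect,
              auc_intercept = auc_intercept, auc_slope = auc_slope,
              auc_noise_sd = auc_noise_sd, n_patients = n_patients,
              label_noise_sd = label_noise_sd)
  counts <- c("n_genes", "k", "samples_per_subtype", "n_normals",
              "block_size", "sig_size", "n_drugs", "n_reversers",
              "n_patients")
  for (nm in counts) if (cfg[[nm]] <= 0)
    stop(nm, " must be positive", call. = FALSE)
  if (n_reversers > n_drugs)
    stop("n_reversers cannot exceed n_drugs", call. = FALSE)
  if (n_genes < k * block_size + 2L * sig_size)
    stop("n_genes too small for the requested subtype blocks and signature",
         call. = FALSE)
  class(cfg) <- "scenario_config"
  cfg
}

#' Simulate a tumor cohort with planted subtypes and disease signature
#'
#' Per-gene baselines are log-normal (normal on the log2 scale). Each
#' subtype up-shifts a disjoint marker block of genes by `shift`; the
#' planted disease signature shifts `sig_size` genes up and `sig_size` down
#' by `activity * sig_effect` relative to normals, where each tumor's
#' activity is drawn uniformly from `sig_activity_range`. Per sample, Gaussian
#' noise (SD `noise_sd`) perturbs the log2 mean, an optional contamination
#' fraction alpha ~ U(`alpha_range`) mixes the tumor's linear-scale mean
#' with the normal mean profile, and observed counts are Poisson around the
#' linear-scale mean. An extra held-out patient sample (subtype 1, never
#' part of the cohort) is generated the same way.
#'
#' @param cfg a [scenario_config()].
#' @return list with `cohort` and `normals` (count `expr_matrix`),
#'   `patient` (one-column count `expr_matrix`), and `truth`: list with
#'   `labels` (planted subtype per cohort sample), `sig_up`, `sig_down`,
#'   `activity` (per-tumor signature activity), `alphas`,
#'   `patient_subtype`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    base <- stats::rnorm(cfg$n_genes, mean = 7, sd = 1.5)
    names(base) <- genes

    blocks <- split(genes[seq_len(cfg$k * cfg$block_size)],
                    rep(seq_len(cfg$k), each = cfg$block_size))
    sig_start <- cfg$k * cfg$block_size
    sig_up <- genes[sig_start + seq_len(cfg$sig_size)]
    sig_down <- genes[sig_start + cfg$sig_size + seq_len(cfg$sig_size)]

    normal_mu <- base                        # log2 mean of the normal tissue
    tumor_mu <- function(subtype, activity) {
      mu <- base
      mu[blocks[[subtype]]] <- mu[blocks[[subtype]]] + cfg$shift
      mu[sig_up] <- mu[sig_up] + activity * cfg$sig_effect
      mu[sig_down] <- mu[sig_down] - activity * cfg$sig_effect
      mu
    }

    n_tumors <- cfg$k * cfg$samples_per_subtype
    labels <- rep(seq_len(cfg$k), each = cfg$samples_per_subtype)
    activity <- stats::runif(n_tumors, cfg$sig_activity_range[1L],
                             cfg$sig_activity_range[2L])
    alphas <- stats::runif(n_tumors, cfg$alpha_range[1L], cfg$alpha_range[2L])
    normal_lin_mean <- 2^normal_mu

    draw_tumor <- function(subtype, activity, alpha) {
      mu <- tumor_mu(subtype, activity) + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
      lin <- (1 - alpha) * 2^mu + alpha * normal_lin_mean
      stats::rpois(cfg$n_genes, lin)
    }
    cohort <- vapply(seq_len(n_tumors),
                     function(i) draw_tumor(labels[i], activity[i], alphas[i]),
                     numeric(cfg$n_genes))
    dimnames(cohort) <- list(genes, sprintf("T%03d", seq_len(n_tumors)))
    names(labels) <- names(alphas) <- names(activity) <- colnames(cohort)

    normals <- vapply(seq_len(cfg$n_normals), function(i) {
      mu <- normal_mu + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
      stats::rpois(cfg$n_genes, 2^mu)
    }, numeric(cfg$n_genes))
    dimnames(normals) <- list(genes, sprintf("N%03d", seq_len(cfg$n_normals)))

    patient <- matrix(draw_tumor(1L, 1, mean(cfg$alpha_range)),
                      dimnames = list(genes, "PT1"))

    list(cohort = expression_matrix(cohort, "counts"),
         normals = expression_matrix(normals, "counts"),
         patient = expression_matrix(patient, "counts"),
         truth = list(labels = labels, sig_up = sig_up, sig_down = sig_down,
                      activity = activity, alphas = alphas,
                      patient_subtype = 1L, subtype_blocks = blocks))
  })
}

#' Simulate a drug perturbation library with planted reversers
#'
#' Each drug gets one record per dose/time combination of the grid
#' (including the 10 uM / 24 h reference). A reverser drug's ranking pushes
#' the signature's up genes toward the bottom and its down genes toward the
#' top by shifting a standard-normal gene score by `pert_effect` times the
#' condition strength; the strength is 1 at the reference and is halved for
#' a low dose (< 10 uM) and halved again for a short duration (< 24 h),
#' emulating the dose-time dependence of perturbation assays. Non-reverser
#' rankings are uniform random permutations. Reversers additionally carry a
#' drug-specific potency in (0.6, 1\], so reversal strengths differ across
#' reversers.
#'
#' @param cfg a [scenario_config()].
#' @param sig_up,sig_down the planted signature gene sets.
#' @param universe gene universe of the rankings (default: all cfg genes).
#' @return list with `library` (a [perturbation_library()]), `reversers`
#'   (drug ids) and `strength` (named per-drug planted reversal strength:
#'   0 for non-reversers, negative for reversers - more negative = stronger
#'   reversal).
#' @export
simulate_perturbation_library <- function(cfg, sig_up, sig_down,
                                          universe = sprintf("g%04d", seq_len(cfg$n_genes))) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (length(sig_up) + length(sig_down) > length(universe))
    stop("signature larger than the gene universe", call. = FALSE)
  n <- length(universe)
  drugs <- sprintf("drug%02d", seq_len(cfg$n_drugs))
  reversers <- drugs[seq_len(cfg$n_reversers)]
  potency <- stats::setNames(rep(0, cfg$n_drugs), drugs)
  potency[reversers] <- seq(0.6, 1, length.out = cfg$n_reversers)
  up_idx <- match(intersect(sig_up, universe), universe)
  down_idx <- match(intersect(sig_down, universe), universe)

  records <- list()
  with_seed(cfg$seed + 1L, {
    for (d in drugs) {
      for (dose in cfg$doses) for (time in cfg$times) {
        strength <- potency[[d]] *
          (if (dose < 10) 0.5 else 1) * (if (time < 24) 0.5 else 1)
        score <- stats::rnorm(n)
        if (strength > 0) {
          score[up_idx] <- score[up_idx] - cfg$pert_effect * strength
          score[down_idx] <- score[down_idx] + cfg$pert_effect * strength
        }
        ranking <- stats::setNames(
          as.integer(rank(-score, ties.method = "first")), universe)
        records[[length(records) + 1L]] <-
          list(drug = d, cell_line = "CL-1", dose_um = dose, time_h = time,
               ranking = ranking)
      }
    }
  })
  list(library = perturbation_library(records, universe),
       reversers = reversers,
       strength = -potency)
}

#' Simulate drug sensitivity and patient response labels
#'
#' AUCs follow the linear link
#' `AUC = clip(intercept + slope * strength + N(0, noise_sd), 0, 1)` per
#' drug, where `strength` is the planted per-drug reversal strength
#' (negative for reversers), so with a positive slope stronger reversers
#' get lower AUCs. Patient response labels for one focal drug come from a
#' per-patient score (standard normal across patients) thresholded at its
#' median after adding Gaussian noise of SD `label_noise_sd`: lower noisy
#' score = responder.
#'
#' @param cfg a [scenario_config()].
#' @param strength named per-drug reversal strength from
#'   [simulate_perturbation_library()].
#' @param cell_line cell line id the AUCs are recorded on.
#' @return list with `sensitivity` (data.frame drug, cell_line, auc),
#'   `scores` (per-patient score of the focal drug) and `labels`
#'   (responder / non-responder per patient).
#' @export
simulate_sensitivity_and_response <- function(cfg, strength,
                                              cell_line = "CL-1") {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed + 2L, {
    auc <- cfg$auc_intercept + cfg$auc_slope * strength +
      stats::rnorm(length(strength), 0, cfg$auc_noise_sd)
    auc <- pmin(pmax(auc, 0), 1)
    sens <- data.frame(drug = names(strength), cell_line = cell_line,
                       auc = unname(auc), stringsAsFactors = FALSE)

    scores <- stats::setNames(stats::rnorm(cfg$n_patients),
                              sprintf("P%03d", seq_len(cfg$n_patients)))
    latent <- scores + stats::rnorm(cfg$n_patients, 0, cfg$label_noise_sd)
    labels <- ifelse(latent < stats::median(latent),
                     "responder", "non-responder")
    names(labels) <- names(scores)
    list(sensitivity = sens, scores = scores, labels = labels)
  })
}

#' Write a full synthetic scenario to disk
#'
#' Materializes every file the pipeline consumes: cohort/normals/patient
#' expression TSVs, the perturbation library TSV, the sensitivity CSV, the
#' planted signature as GMT, and the truth/labels as JSON.
#'
#' @param cfg a [scenario_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the list of generated objects.
#' @export
write_scenario <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_cohort(cfg)
  pert <- simulate_perturbation_library(cfg, sim$truth$sig_up,
                                        sim$truth$sig_down)
  sr <- simulate_sensitivity_and_response(cfg, pert$strength)
  write_expression_matrix(sim$cohort, file.path(dir, "cohort.tsv"))
  write_expression_matrix(sim$normals, file.path(dir, "normals.tsv"))
  write_expression_matrix(sim$patient, file.path(dir, "patient.tsv"))
  write_perturbation_library(pert$library, file.path(dir, "perturbations.tsv"))
  utils::write.csv(sr$sensitivity, file.path(dir, "sensitivity.csv"),
                   row.names = FALSE)
  write_gmt(stats::setNames(list(sim$truth$sig_up, sim$truth$sig_down),
                            c("planted_up", "planted_down")),
            file.path(dir, "planted_signature.gmt"))
  jsonlite::write_json(list(labels = as.list(sim$truth$labels),
                            reversers = pert$reversers,
                            response = as.list(sr$labels)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(list(sim = sim, pert = pert, response = sr))
}
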