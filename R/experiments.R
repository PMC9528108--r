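# Canned study-condition experiments used by the test suite and the
# acceptance script. Problem sizes are desk-scale: small images, tiny
# backbones, and a subset of fold rotations, chosen so a full run fits in
# minutes on one CPU while preserving the statistical structure under
# study.

#' Detection study on clean phantoms
#'
#' Generates destruction-free phantom hands, trains one detector per the
#' supplied config on `n_train` hand images, and evaluates the correct
#' detection rate and scale-normalized distance error on `n_test` held-out
#' hands.
#'
#' @param seed Integer seed controlling generation and training.
#' @param assessment `"erosion"` or `"jsn"`.
#' @param n_train,n_test Hand-image counts.
#' @param image_size Phantom resolution.
#' @param input_size,sigma,max_epochs Detector settings.
#' @param dir Dataset directory (default: under `tempdir()`).
#' @return List with `rate` (overall correct detection rate), `dist_mean`
#'   (mean scale-normalized distance error), `sigma_normalized` (the
#'   heatmap sigma expressed in the same scale-normalized full-resolution
#'   units as the distance error), `summary` and `model`.
#' @export
detection_study <- function(seed = 1L, assessment = "erosion",
                            n_train = 20, n_test = 10, image_size = 256,
                            input_size = 64, sigma = 3, max_epochs = 150,
                            dir = NULL) {
  if (is.null(dir)) {
    dir <- file.path(tempdir(), paste0("shs_detstudy_", assessment, "_", seed))
  }
  n_hands <- n_train + n_test
  cfg <- phantom_config(image_size = image_size, prevalence = 0,
                        noise_sd = 0.03,
                        seed = derive_seed(seed, "det_phantom"))
  manifest <- if (file.exists(file.path(dir, "manifest.csv"))) {
    read_manifest(file.path(dir, "manifest.csv"))
  } else {
    generate_dataset(cfg, ceiling(n_hands / 2), 1, dir)
  }
  dcfg <- detector_config(assessment, input_size = input_size, sigma = sigma,
                          max_epochs = max_epochs,
                          seed = derive_seed(seed, "det_train"))
  res <- run_detection_experiment(manifest, dcfg,
                                  train_idx = seq_len(n_train),
                                  test_idx = (n_train + 1):n_hands)
  s <- res$eval$summary
  tot <- s[s$group == "All joints" & s$class == "total", ]
  # sigma in the error's units: input px -> original px -> normalized px
  mean_scale <- 100 / (0.138 * image_size)  # L_ref over nominal phalanx length
  list(rate = tot$rate, dist_mean = tot$dist_mean,
       sigma_normalized = sigma * (image_size / input_size) * mean_scale,
       summary = s, model = res$model)
}

#' Contextual-advantage study
#'
#' The desk-scale analog of comparing the independent (SISO) classifier
#' with the contralateral-pair (MIMO local) classifier. Phantom hands are
#' generated with a given bilateral label correlation, weak destruction
#' contrast and benign margin mimics; joints of one group are cropped at
#' ground-truth centers, and both architectures are trained with a shared
#' feature-extractor initialization under patient-disjoint rotations.
#'
#' @param seed Integer seed.
#' @param rho_sym Bilateral latent correlation of the generated labels.
#' @param n_patients Cohort size.
#' @param contrast Destruction-signature contrast (weak by default so
#'   single-view classification of mild lesions is ambiguous).
#' @param group,assessment Joint group under study.
#' @param n_rotations Number of fold rotations actually run (of `k = 4`).
#' @param input_side,max_epochs,lr,dropout Classifier settings.
#' @param n_total Augmentation-balanced crop budget per model.
#' @return List with `auc_siso`, `auc_mimo_local`, `gap`
#'   (MIMO minus SISO pooled test PR-AUC) and the per-architecture results.
#' @export
contextual_advantage_study <- function(seed = 1L, rho_sym = 0.9,
                                       n_patients = 60, contrast = 0.5,
                                       group = "MCP", assessment = "erosion",
                                       n_rotations = 2, input_side = 32,
                                       max_epochs = 60, lr = 1.5e-3,
                                       dropout = 0.2, n_total = 600L) {
  dir <- file.path(tempdir(),
                   sprintf("shs_ctx_%s_%s_%d", seed, rho_sym * 100, n_patients))
  cfg <- phantom_config(image_size = 256, prevalence = 0.3,
                        rho_sym = rho_sym, rho_grp = 0, rho_pat = 0,
                        contrast = contrast, noise_sd = 0.05,
                        seed = derive_seed(seed, "ctx_phantom"))
  manifest <- if (file.exists(file.path(dir, "manifest.csv"))) {
    read_manifest(file.path(dir, "manifest.csv"))
  } else {
    generate_dataset(cfg, n_patients, 1, dir)
  }
  crops <- crops_from_manifest(manifest, assessment)
  members <- group_members(assessment, group)$name
  crops <- Filter(function(cr) cr$name %in% members, crops)
  folds <- make_patient_folds(unique(manifest$patient_id), k = 4,
                              seed = derive_seed(seed, "ctx_folds"))
  folds$rotations <- folds$rotations[seq_len(n_rotations)]
  pol <- augmentation_policy(n_total = n_total,
                             seed = derive_seed(seed, "ctx_policy"))
  mkcfg <- function(arch) {
    classifier_config(arch, assessment, group, input_side = input_side,
                      max_epochs = max_epochs, lr = lr, dropout = dropout,
                      seed = derive_seed(seed, paste0("ctx_", arch)))
  }
  cv <- compare_architectures(crops, folds,
                              list(siso = mkcfg("siso"),
                                   mimo_local = mkcfg("mimo_local")), pol)
  auc_of <- function(a) {
    m <- cv[[a]]$metrics
    m$pr_auc[m$group == "All joints"]
  }
  list(auc_siso = auc_of("siso"), auc_mimo_local = auc_of("mimo_local"),
       gap = auc_of("mimo_local") - auc_of("siso"), results = cv)
}
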