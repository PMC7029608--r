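#' Featurize a loaded dataset
#'
#' Runs both encoding arms: per-RNA k-mer/SVD vectors and per-protein
#' PWM/Legendre-moment vectors.
#'
#' @param rnas named character vector of RNA sequences.
#' @param proteins named character vector of protein sequences (already
#'   length-filtered).
#' @param pssm_dir optional directory of PSI-BLAST ASCII PSSM files.
#' @param k RNA k-mer window (default 4).
#' @param max_order Legendre moment order cap (default 25).
#' @param pwm_norm PWM normalization, see [normalize_pwm()].
#' @return list with `rna_features` (n x 4^k) and `protein_moments`
#'   (n x (max_order+1)^2).
#' @export
featurize <- function(rnas, proteins, pssm_dir = NULL, k = 4L,
                      max_order = 25L,
                      pwm_norm = c("logistic", "minmax")) {
  pwm_norm <- match.arg(pwm_norm)
  list(rna_features = encode_rna(rnas, k = k),
       protein_moments = encode_proteins(
         protein_profiles(proteins, pssm_dir, pwm_norm),
         max_order = max_order))
}

#' Run the full pipeline end to end
#'
#' Loads (or synthesizes) sequences and pairs, filters proteins, builds
#' both feature arms, runs stratified cross-validation of the stacked
#' ensemble, and writes per-fold metrics, held-out ROC points and a JSON
#' run manifest to `out_dir`.
#'
#' @param rna_fasta,protein_fasta,pairs_file input paths; all three may be
#'   `NULL` if `synth` is given.
#' @param synth optional [synth_config()]: generate the inputs instead of
#'   reading them.
#' @param pssm_dir optional directory of per-protein `.pssm` files.
#' @param out_dir output directory (created); `NULL` for no file output.
#' @param k,max_order,n_components,pwm_norm feature-stage parameters.
#' @param min_protein_len protein length filter (default 51: keep > 50).
#' @param n_folds,strategy,svd_scope,configs evaluation-stage parameters,
#'   see [cross_validate()].
#' @param seed run seed, recorded in the manifest.
#' @return the run manifest (list), invisibly; its `cv` element is the
#'   [cross_validate()] result.
#' @export
run_pipeline <- function(rna_fasta = NULL, protein_fasta = NULL,
                         pairs_file = NULL, synth = NULL,
                         pssm_dir = NULL, out_dir = NULL,
                         k = 4L, max_order = 25L, n_components = 500L,
                         pwm_norm = "logistic", min_protein_len = 51L,
                         n_folds = 5L, strategy = "stacked",
                         svd_scope = "fold", configs = default_configs(),
                         seed = 1L) {
  if (!is.null(synth)) {
    ds <- synth_generate(synth, out_dir = NULL)
    rnas <- ds$rnas
    prots_all <- ds$proteins
    flt <- filter_proteins(prots_all, min_protein_len)
    pairs <- ds$pairs[!(ds$pairs$protein_id %in% flt$dropped_ids), ,
                      drop = FALSE]
  } else {
    if (is.null(rna_fasta) || is.null(protein_fasta) || is.null(pairs_file)) {
      stop("run_pipeline: provide either synth= or all three input paths")
    }
    rnas <- read_fasta(rna_fasta, "rna")
    prots_all <- read_fasta(protein_fasta, "protein")
    flt <- filter_proteins(prots_all, min_protein_len)
    pairs <- read_pairs(pairs_file, flt$kept, rnas, flt$dropped_ids)
  }
  feats <- featurize(rnas[unique(pairs$rna_id)],
                     flt$kept[unique(pairs$protein_id)],
                     pssm_dir = pssm_dir, k = k, max_order = max_order,
                     pwm_norm = pwm_norm)
  cv <- cross_validate(pairs, feats$rna_features, feats$protein_moments,
                       n_folds = n_folds, seed = seed, configs = configs,
                       n_components = n_components, svd_scope = svd_scope,
                       strategy = strategy)
  manifest <- list(
    package = as.character(utils::packageVersion("rpstack")),
    seed = seed,
    parameters = list(k = k, max_order = max_order,
                      n_components = n_components, pwm_norm = pwm_norm,
                      min_protein_len = min_protein_len, n_folds = n_folds,
                      strategy = strategy, svd_scope = svd_scope),
    counts = list(n_rna = length(unique(pairs$rna_id)),
                  n_protein = length(unique(pairs$protein_id)),
                  n_dropped_protein = length(flt$dropped_ids),
                  n_pairs = nrow(pairs),
                  rna_feature_dim = ncol(feats$rna_features),
                  moment_dim = ncol(feats$protein_moments),
                  pair_feature_dim = min(n_components,
                                         ncol(feats$protein_moments)) +
                                     ncol(feats$rna_features)),
    summary = list(mean = as.list(cv$mean), sd = as.list(cv$sd)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cv_results(cv, file.path(out_dir, "cv_metrics.tsv"))
    write.table(roc_points(pairs$label, cv$scores),
                file.path(out_dir, "roc_points.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest$cv <- cv
  invisible(manifest)
}
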