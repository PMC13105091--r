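# Synthetic molecules, receptors, and planted interaction structure. The
# generators emulate the shapes of the two kinds of study data: dense
# full-factorial electrophysiology panels with continuous responses, and
# sparse, imbalanced binary screens with quality tiers. Responses are planted
# through a bilinear model over transparent reference features, so every
# downstream stage can be tested against known ground truth.

# Enumerate the SMILES template grammar: linear alkanes, alcohols, esters,
# ketones, aldehydes, amines, ethers, nitriles, and substituted benzenes.
.molecule_grammar <- function() {
  rep_c <- function(k) strrep("C", k)
  out <- c(
    vapply(1:15, rep_c, character(1)),                                    # alkanes
    vapply(1:15, function(k) paste0(rep_c(k), "O"), character(1)),        # alcohols
    as.vector(outer(0:6, 1:6, function(i, j)
      paste0(rep_c(i), "C(=O)O", rep_c(j)))),                             # esters
    as.vector(outer(1:6, 1:6, function(i, j)
      paste0(rep_c(i), "C(=O)", rep_c(j)))),                              # ketones
    vapply(1:10, function(k) paste0(rep_c(k), "C=O"), character(1)),      # aldehydes
    vapply(1:10, function(k) paste0(rep_c(k), "N"), character(1)),        # amines
    as.vector(outer(1:6, 1:6, function(i, j)
      paste0(rep_c(i), "O", rep_c(j)))),                                  # ethers
    vapply(1:8, function(k) paste0(rep_c(k), "C#N"), character(1)),       # nitriles
    vapply(0:8, function(k) paste0(rep_c(k), "c1ccccc1"), character(1)),  # benzenes
    vapply(0:8, function(k) paste0(rep_c(k), "Oc1ccccc1"), character(1)), # aryl ethers
    vapply(1:8, function(k) paste0(rep_c(k), "C(=O)N"), character(1))     # amides
  )
  unique(out)
}

#' Generate synthetic odorant molecules
#'
#' Draws `n` distinct, syntactically valid SMILES strings from a fixed
#' template grammar of small volatile-like molecules (alkanes, alcohols,
#' esters, ketones, aldehydes, amines, ethers, nitriles, substituted
#' aromatics). Deterministic in `seed`.
#'
#' @param n number of molecules (up to the grammar capacity).
#' @param seed integer seed.
#' @return data.frame with columns `odorant_id`, `smiles`.
#' @export
gen_molecules <- function(n, seed = 1L) {
  pool <- .molecule_grammar()
  if (n > length(pool))
    stop("n = ", n, " exceeds the grammar capacity of ", length(pool),
         " distinct molecules")
  pick <- .with_private_seed(seed, function() sample(pool, n))
  data.frame(odorant_id = sprintf("odor_%03d", seq_len(n)),
             smiles = pick, stringsAsFactors = FALSE)
}

#' Generate synthetic receptor sequences
#'
#' Uniform-random amino-acid sequences over the 20 canonical residues;
#' deterministic in `seed`.
#'
#' @param m number of receptors.
#' @param length sequence length (>= 5).
#' @param seed integer seed.
#' @return data.frame with columns `receptor_id`, `sequence`.
#' @export
gen_receptors <- function(m, length = 50L, seed = 1L) {
  if (length < 5) stop("length must be >= 5")
  seqs <- .with_private_seed(seed, function()
    vapply(seq_len(m), function(i)
      paste(sample(.AA_ALPHABET, length, replace = TRUE), collapse = ""),
      character(1)))
  data.frame(receptor_id = sprintf("OR_%03d", seq_len(m)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Define a planted interaction model
#'
#' Responses are planted as the bilinear form `u' M v` where
#' `u = (1, chem features)` and `v = (1, receptor features)`; the leading 1s
#' let `M` encode additive odorant-only / receptor-only terms as its first
#' row and column. Chemical features default to normalized character counts
#' of the SMILES string and receptor features to amino-acid composition, so
#' the planted signal is recoverable from the raw strings by any competent
#' encoder.
#'
#' @param M interaction matrix, `(1 + d_chem) x (1 + d_prot)`.
#' @param chem_feature_fn function: SMILES vector -> feature matrix.
#' @param prot_feature_fn function: sequence vector -> feature matrix.
#' @param noise_sd Gaussian noise SD added to the (unit-variance) signal.
#' @param link `"identity"` for continuous responses or
#'   `"threshold_logistic"` for binary labels.
#' @param positive_rate_target target positive fraction under the threshold
#'   link (labels cut at the matching empirical latent quantile).
#' @return object of class `planted_model`.
#' @export
planted_model <- function(M, chem_feature_fn = NULL, prot_feature_fn = NULL,
                          noise_sd = 0.1,
                          link = c("identity", "threshold_logistic"),
                          positive_rate_target = 0.3) {
  link <- match.arg(link)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(chem_feature_fn)) {
    cf <- count_featurizer(normalize = TRUE)
    chem_feature_fn <- function(smiles) cf(smiles)
  }
  if (is.null(prot_feature_fn)) {
    prot_feature_fn <- function(seqs) {
      f <- kmer_protein_featurizer(1)
      f(data.frame(receptor_id = as.character(seq_along(seqs)),
                   sequence = seqs))$values
    }
  }
  structure(list(M = as.matrix(M), chem_feature_fn = chem_feature_fn,
                 prot_feature_fn = prot_feature_fn, noise_sd = noise_sd,
                 link = link, positive_rate_target = positive_rate_target),
            class = "planted_model")
}

#' Convenience planted interaction matrices
#'
#' `planted_bilinear` draws a dense low-rank interaction structure (plus
#' additive odorant and receptor terms); `planted_additive` keeps only the
#' additive first row and column, making the response exactly linear in the
#' concatenated `(chem, prot)` features; `planted_receptor_only` keeps only
#' the receptor column, producing responses that carry no chemical
#' information at all.
#'
#' @param d_chem,d_prot feature dimensionalities (excluding the leading 1).
#' @param rank rank of the interaction block (`planted_bilinear`).
#' @param seed integer seed.
#' @return an interaction matrix suitable for [planted_model()].
#' @export
planted_bilinear <- function(d_chem, d_prot, rank = 2L, seed = 1L) {
  .with_private_seed(seed, function() {
    M <- matrix(0, d_chem + 1, d_prot + 1)
    M[1, ] <- stats::rnorm(d_prot + 1)
    M[, 1] <- stats::rnorm(d_chem + 1)
    A <- matrix(stats::rnorm((d_chem) * rank), d_chem, rank)
    B <- matrix(stats::rnorm((d_prot) * rank), d_prot, rank)
    M[-1, -1] <- A %*% t(B)
    M
  })
}

#' @rdname planted_bilinear
#' @export
planted_additive <- function(d_chem, d_prot, seed = 1L) {
  .with_private_seed(seed, function() {
    M <- matrix(0, d_chem + 1, d_prot + 1)
    M[1, ] <- stats::rnorm(d_prot + 1)
    M[-1, 1] <- stats::rnorm(d_chem)
    M
  })
}

#' @rdname planted_bilinear
#' @export
planted_receptor_only <- function(d_chem, d_prot, seed = 1L) {
  .with_private_seed(seed, function() {
    M <- matrix(0, d_chem + 1, d_prot + 1)
    M[1, -1] <- stats::rnorm(d_prot)
    M
  })
}

#' Generate a full-factorial interaction panel
#'
#' Pairs every odorant with every receptor (n_odorants x n_receptors
#' interactions) and plants responses `u_i' M v_j + eps`,
#' `eps ~ N(0, noise_sd^2)`. When `scale_signal = TRUE` (default) the
#' noiseless signal is standardized to zero mean and unit SD before noise is
#' added, so `noise_sd` reads as a relative noise level; the effective `M`
#' after scaling is what `truth$M` records. Under the
#' `"threshold_logistic"` link, latent values are cut at the empirical
#' quantile that hits the target positive rate.
#'
#' @param n_odorants,n_receptors panel dimensions.
#' @param planted a [planted_model()].
#' @param seed integer seed (molecules, receptors, and noise derive
#'   sub-seeds from it).
#' @param receptor_length sequence length for generated receptors.
#' @param scale_signal standardize the noiseless signal (see above).
#' @return list with `dataset` (an [interaction_dataset()]) and `truth`
#'   (list `M`, `U`, `V`, `noise_sd`, `signal`): the planted ground truth for
#'   recovery tests.
#' @export
gen_panel <- function(n_odorants, n_receptors, planted = NULL, seed = 1L,
                      receptor_length = 12L, scale_signal = TRUE) {
  if (is.null(planted)) {
    cf <- count_featurizer(normalize = TRUE)
    d_chem <- length(cf("C")[1, ])
    planted <- planted_model(planted_bilinear(d_chem, 20, seed = seed))
  }
  odorants <- gen_molecules(n_odorants, seed = seed + 1L)
  receptors <- gen_receptors(n_receptors, length = receptor_length,
                             seed = seed + 2L)
  U <- cbind(1, planted$chem_feature_fn(odorants$smiles))
  V <- cbind(1, planted$prot_feature_fn(receptors$sequence))
  if (ncol(U) != nrow(planted$M) || ncol(V) != ncol(planted$M))
    stop("planted M is ", nrow(planted$M), " x ", ncol(planted$M),
         " but features give ", ncol(U), " x ", ncol(V))
  S <- U %*% planted$M %*% t(V)   # odorants x receptors
  M_eff <- planted$M
  if (scale_signal) {
    mu <- mean(S); sdev <- stats::sd(as.vector(S))
    if (sdev == 0) stop("planted signal is constant; cannot scale")
    S <- (S - mu) / sdev
    M_eff <- M_eff / sdev
    M_eff[1, 1] <- M_eff[1, 1] - mu / sdev
  }
  eps <- .with_private_seed(seed + 3L, function()
    matrix(stats::rnorm(length(S), sd = planted$noise_sd), nrow(S)))
  R <- S + eps
  grid <- expand.grid(oi = seq_len(n_odorants), ri = seq_len(n_receptors))
  latent <- R[cbind(grid$oi, grid$ri)]
  if (planted$link == "identity") {
    it <- data.frame(odorant_id = odorants$odorant_id[grid$oi],
                     receptor_id = receptors$receptor_id[grid$ri],
                     response = latent, stringsAsFactors = FALSE)
    ds <- interaction_dataset(odorants, receptors, it, mode = "regression")
  } else {
    cut <- stats::quantile(latent, 1 - planted$positive_rate_target)
    it <- data.frame(odorant_id = odorants$odorant_id[grid$oi],
                     receptor_id = receptors$receptor_id[grid$ri],
                     label = as.integer(latent > cut),
                     stringsAsFactors = FALSE)
    ds <- interaction_dataset(odorants, receptors, it, mode = "classification")
  }
  list(dataset = ds,
       truth = list(M = M_eff, U = U, V = V, noise_sd = planted$noise_sd,
                    signal = S))
}

#' Generate a sparse, imbalanced binary screen
#'
#' Samples a random subset of the odorant x receptor grid at the given
#' density and assigns binary labels by thresholding a latent planted score
#' at the empirical quantile matching `positive_rate` (so the realized
#' positive fraction matches the target up to rounding). Each record carries
#' a quality tier drawn from `tiers`.
#'
#' @param n_odorants,n_receptors grid dimensions.
#' @param density fraction of the grid measured, in (0, 1).
#' @param positive_rate target positive fraction, in (0, 1).
#' @param tiers named numeric vector of tier sampling probabilities.
#' @param seed integer seed.
#' @param receptor_length sequence length for generated receptors.
#' @return list with `dataset` (classification-mode
#'   [interaction_dataset()]) and `truth`.
#' @export
gen_sparse_screen <- function(n_odorants, n_receptors, density = 0.05,
                              positive_rate = 0.2,
                              tiers = c(ec50 = 0.1, primary = 0.5,
                                        secondary = 0.4),
                              seed = 1L, receptor_length = 12L) {
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (positive_rate <= 0 || positive_rate >= 1)
    stop("positive_rate must be in (0, 1)")
  odorants <- gen_molecules(n_odorants, seed = seed + 1L)
  receptors <- gen_receptors(n_receptors, length = receptor_length,
                             seed = seed + 2L)
  cf <- count_featurizer(normalize = TRUE)
  d_chem <- ncol(cf("C"))
  pm <- planted_model(planted_bilinear(d_chem, 20, seed = seed),
                      noise_sd = 0.5)
  U <- cbind(1, pm$chem_feature_fn(odorants$smiles))
  V <- cbind(1, pm$prot_feature_fn(receptors$sequence))
  S <- U %*% pm$M %*% t(V)
  S <- (S - mean(S)) / stats::sd(as.vector(S))
  total <- n_odorants * n_receptors
  n_pairs <- max(1L, round(density * total))
  .with_private_seed(seed + 3L, function() {
    pick <- sample.int(total, n_pairs)
    oi <- ((pick - 1L) %% n_odorants) + 1L
    ri <- ((pick - 1L) %/% n_odorants) + 1L
    latent <- S[cbind(oi, ri)] + stats::rnorm(n_pairs, sd = pm$noise_sd)
    cut <- stats::quantile(latent, 1 - positive_rate)
    tier <- sample(names(tiers), n_pairs, replace = TRUE,
                   prob = unname(tiers))
    it <- data.frame(odorant_id = odorants$odorant_id[oi],
                     receptor_id = receptors$receptor_id[ri],
                     label = as.integer(latent > cut),
                     tier = tier, stringsAsFactors = FALSE)
    ds <- interaction_dataset(odorants, receptors, it,
                              mode = "classification")
    list(dataset = ds,
         truth = list(M = pm$M, U = U, V = V, cut = unname(cut)))
  })
}
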