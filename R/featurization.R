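# Featurizer registry -------------------------------------------------------

# Package-level default registry, populated in .onLoad.
.default_registry <- new.env(parent = emptyenv())

.registry_store <- function(registry) {
  if (is.null(registry)) .default_registry else registry
}

#' Describe a featurizer
#'
#' @param name unique registry name.
#' @param kind one of `"physchem"`, `"transformer"`, `"gnn"`, `"random"`,
#'   `"reference"`.
#' @param dim output dimensionality (>= 1).
#' @param params named list of featurizer parameters (recorded for
#'   reproducibility).
#' @return object of class `featurizer_spec`.
#' @export
featurizer_spec <- function(name, kind = c("reference", "physchem",
                                           "transformer", "gnn", "random"),
                            dim, params = list()) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  dim <- as.integer(dim)
  if (dim < 1) stop("dim must be >= 1")
  structure(list(name = name, kind = kind, dim = dim, params = params),
            class = "featurizer_spec")
}

#' Create an empty featurizer registry
#'
#' Most code uses the package-wide default registry (pass `registry = NULL`);
#' a private registry is useful for isolated experiments.
#' @return an environment usable as the `registry` argument elsewhere.
#' @export
new_featurizer_registry <- function() new.env(parent = emptyenv())

#' Register a molecule featurizer
#'
#' @param spec a [featurizer_spec()].
#' @param fn function taking a character vector of SMILES and returning an
#'   n x dim numeric matrix with rows aligned to the input.
#' @param registry optional registry environment (default: package registry).
#' @return `spec`, invisibly.
#' @export
register_featurizer <- function(spec, fn, registry = NULL) {
  stopifnot(inherits(spec, "featurizer_spec"), is.function(fn))
  store <- .registry_store(registry)
  if (spec$name %in% names(store))
    stop("featurizer `", spec$name, "` is already registered")
  assign(spec$name, list(spec = spec, fn = fn,
                         order = length(names(store)) + 1L),
         envir = store)
  invisible(spec)
}

#' List registered featurizers
#' @param registry optional registry environment.
#' @return character vector of names in insertion order.
#' @export
list_featurizers <- function(registry = NULL) {
  store <- .registry_store(registry)
  nm <- names(store)
  ord <- vapply(nm, function(n) store[[n]]$order, integer(1))
  nm[order(ord)]
}

#' Fetch a registered featurizer
#' @param name registry name.
#' @param registry optional registry environment.
#' @return list with elements `spec` and `fn`.
#' @export
get_featurizer <- function(name, registry = NULL) {
  store <- .registry_store(registry)
  if (!name %in% names(store))
    stop("no featurizer named `", name, "`; registered: ",
         paste(list_featurizers(registry), collapse = ", "))
  store[[name]][c("spec", "fn")]
}

#' Featurize a set of odorants
#'
#' Applies a registered featurizer to odorant records, returning rows aligned
#' to the input order. Featurizers are pure functions of their parameters and
#' input: repeated calls are bit-identical.
#'
#' @param name registered featurizer name.
#' @param odorants data.frame with columns `odorant_id`, `smiles` (e.g. the
#'   `odorants` element of an [interaction_dataset()]).
#' @param registry optional registry environment.
#' @return a [representation_matrix()] named after the featurizer.
#' @export
featurize_molecules <- function(name, odorants, registry = NULL) {
  f <- get_featurizer(name, registry)
  m <- f$fn(odorants$smiles)
  m <- as.matrix(m)
  if (nrow(m) != nrow(odorants))
    stop("featurizer `", name, "` returned ", nrow(m), " rows for ",
         nrow(odorants), " molecules")
  representation_matrix(m, item_ids = odorants$odorant_id, name = name)
}

# Reference featurizers ------------------------------------------------------

# Characters accepted in SMILES input by the reference featurizers.
.SMILES_CHARSET <- c(LETTERS, letters, as.character(0:9),
                     "(", ")", "[", "]", "=", "#", "@", "+", "-", ".",
                     "/", "\\", "%")

.check_smiles <- function(smiles) {
  for (s in smiles) {
    if (is.na(s) || !nzchar(s)) stop("empty SMILES string")
    ch <- strsplit(s, "")[[1]]
    if (!all(ch %in% .SMILES_CHARSET))
      stop("unparseable SMILES: `", s, "` (character `",
           ch[!ch %in% .SMILES_CHARSET][1], "`)")
  }
  invisible(TRUE)
}

#' Character-count reference featurizer
#'
#' A deliberately simple, fully self-contained molecular featurizer: each
#' SMILES string is represented by the counts of alphabet characters it
#' contains. The token `"#ring"` in the alphabet counts all digits (ring-bond
#' labels). Useful as a transparent reference space for testing pipelines and
#' planting synthetic signal, not as a chemically meaningful descriptor set.
#'
#' @param alphabet characters to count; `"#ring"` counts digits 0-9.
#' @param normalize divide counts by the string length, giving compositions.
#' @return function: character vector of SMILES -> count matrix.
#' @export
count_featurizer <- function(alphabet = c("C", "c", "O", "N", "=", "(", "#ring"),
                             normalize = FALSE) {
  force(alphabet); force(normalize)
  function(smiles) {
    .check_smiles(smiles)
    out <- matrix(0, length(smiles), length(alphabet),
                  dimnames = list(NULL, alphabet))
    for (i in seq_along(smiles)) {
      ch <- strsplit(smiles[i], "")[[1]]
      for (j in seq_along(alphabet)) {
        out[i, j] <- if (alphabet[j] == "#ring")
          sum(ch %in% as.character(0:9)) else sum(ch == alphabet[j])
      }
      if (normalize) out[i, ] <- out[i, ] / length(ch)
    }
    out
  }
}

# Deterministic 31-bit polynomial rolling hash of a string.
.string_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (cc in v) h <- (h * 131 + cc) %% 2147483563
  as.integer(h)
}

# Run fn with a private RNG stream; global .Random.seed is untouched.
.with_private_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Random-baseline featurizer
#'
#' The lower-bound representation: every molecule is assigned an i.i.d.
#' standard-normal vector. The random stream is keyed to
#' (`seed`, hash of the SMILES string), not to row position, so a molecule
#' receives the same vector in every dataset, call, and fold -- train/test
#' splits therefore see consistent (but chemically meaningless) features.
#'
#' @param dim representation dimensionality.
#' @param seed integer stream seed.
#' @return function: character vector of SMILES -> n x dim matrix.
#' @export
random_featurizer <- function(dim, seed = 1L) {
  dim <- as.integer(dim)
  if (dim < 1) stop("dim must be >= 1")
  force(seed)
  function(smiles) {
    .check_smiles(smiles)
    out <- matrix(0, length(smiles), dim)
    for (i in seq_along(smiles)) {
      h <- (.string_hash(smiles[i]) + as.integer(seed) * 65599) %% 2147483563
      out[i, ] <- .with_private_seed(h, function() stats::rnorm(dim))
    }
    out
  }
}

#' k-mer composition featurizer for receptor sequences
#'
#' Represents each amino-acid sequence by its normalized k-mer count vector
#' of dimension `length(alphabet)^k`. A transparent stand-in for frozen
#' protein-language-model embeddings at desk scale.
#'
#' @param k k-mer length (>= 1).
#' @param alphabet residue alphabet (default: the 20 canonical amino acids).
#' @return function: data.frame of receptor records (columns `receptor_id`,
#'   `sequence`) -> [representation_matrix()].
#' @export
kmer_protein_featurizer <- function(k = 1L, alphabet = .AA_ALPHABET) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  kmers <- alphabet
  if (k > 1) {
    for (i in seq_len(k - 1))
      kmers <- as.vector(outer(kmers, alphabet, paste0))
  }
  function(receptors) {
    seqs <- receptors$sequence
    out <- matrix(0, length(seqs), length(kmers),
                  dimnames = list(NULL, kmers))
    for (i in seq_along(seqs)) {
      s <- toupper(seqs[i])
      n <- nchar(s)
      if (n < k)
        stop("sequence for `", receptors$receptor_id[i],
             "` is shorter than k = ", k)
      subs <- substring(s, 1:(n - k + 1), k:n)
      counts <- table(factor(subs, levels = kmers))
      out[i, ] <- as.numeric(counts) / (n - k + 1)
    }
    representation_matrix(out, item_ids = receptors$receptor_id,
                          name = paste0(k, "mer_composition"))
  }
}

#' Pool a list of token embedding matrices into fixed vectors
#'
#' @param token_list list of T_i x d matrices (non-padding tokens only).
#' @param mode `"mean_tokens"` (average over tokens, default) or
#'   `"first_token"`.
#' @return n x d matrix of pooled vectors.
#' @export
pool_tokens <- function(token_list, mode = c("mean_tokens", "first_token")) {
  mode <- match.arg(mode)
  out <- t(vapply(token_list, function(m) {
    if (mode == "mean_tokens") colMeans(m) else m[1, ]
  }, numeric(ncol(token_list[[1]]))))
  out
}

.onLoad <- function(libname, pkgname) {
  if (!"reference_counts" %in% names(.default_registry)) {
    register_featurizer(
      featurizer_spec("reference_counts", "reference", dim = 7,
                      params = list(alphabet = c("C", "c", "O", "N", "=",
                                                 "(", "#ring"))),
      count_featurizer())
    register_featurizer(
      featurizer_spec("reference_counts_norm", "reference", dim = 7,
                      params = list(normalize = TRUE)),
      count_featurizer(normalize = TRUE))
    register_featurizer(
      featurizer_spec("random64", "random", dim = 64,
                      params = list(seed = 20260927L)),
      random_featurizer(64, seed = 20260927L))
  }
  invisible()
}
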