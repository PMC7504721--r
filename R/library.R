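#' Validate and load a fragment screening library
#'
#' Checks a compound table against the invariants the downstream triage and
#' affinity stages rely on: unique compound ids, positive molecular weights,
#' and membership of each compound in one of the five library subsets
#' (two- and three-dimensional fragment libraries, natural-product-based,
#' serine-protease-inhibitor-biased, and protein-protein-interaction
#' collections).
#'
#' @param table A data frame with columns `id`, `sublibrary`, `mw` and
#'   optionally `heavy_atoms`, `hbd`, `clogp`, `smiles`.
#' @return A tibble of validated compounds (one row per compound). Rejected
#'   rows are dropped and reported in the `rejected` attribute, a tibble with
#'   columns `id`, `row`, `reason`.
#' @examples
#' lib <- load_library(data.frame(
#'   id = c("C1", "C2"), sublibrary = c("2D-FL", "PPI"), mw = c(150, 420)
#' ))
#' attr(lib, "rejected")
#' @export
load_library <- function(table) {
  check_columns(table, c("id", "sublibrary", "mw"), "table")
  tbl <- as_tibble(table)
  for (col in c("heavy_atoms", "hbd", "clogp", "smiles")) {
    if (!col %in% names(tbl)) {
      tbl[[col]] <- if (col == "smiles") NA_character_ else NA_real_
    }
  }
  tbl$id <- as.character(tbl$id)
  tbl$sublibrary <- as.character(tbl$sublibrary)

  dup <- unique(tbl$id[duplicated(tbl$id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate compound id(s): %s", paste(dup, collapse = ", ")))
  }

  reason <- rep(NA_character_, nrow(tbl))
  bad_mw <- !is.finite(tbl$mw) | tbl$mw <= 0
  reason[bad_mw] <- "non-positive molecular weight"
  bad_sub <- !tbl$sublibrary %in% sublibrary_levels() & is.na(reason)
  reason[bad_sub] <- "unknown sublibrary"
  bad_ha <- !is.na(tbl$heavy_atoms) & tbl$heavy_atoms < 1 & is.na(reason)
  reason[bad_ha] <- "heavy-atom count below 1"

  keep <- is.na(reason)
  rejected <- tibble(
    id = tbl$id[!keep],
    row = which(!keep),
    reason = reason[!keep]
  )
  out <- tbl[keep, c("id", "sublibrary", "mw", "heavy_atoms", "hbd", "clogp", "smiles")]
  out$sublibrary <- factor(out$sublibrary, levels = sublibrary_levels())
  attr(out, "rejected") <- rejected
  out
}

#' @rdname load_library
#' @export
sublibrary_levels <- function() c("2D-FL", "3D-FL", "NPB", "SPI", "PPI")

#' Rule-of-three compliance
#'
#' Fragment-likeness filter: molecular weight at most 300 Da, at most 3
#' hydrogen-bond donors, and clogP at most 3. All boundaries are inclusive.
#' Missing descriptors make the verdict indeterminate rather than silently
#' compliant.
#'
#' @param compounds A data frame with columns `mw`, `hbd`, `clogp` (an `id`
#'   column is carried through if present).
#' @param mw_max,hbd_max,clogp_max Criterion boundaries (defaults 300 Da, 3, 3).
#' @return The input tibble with logical columns `ro3_mw`, `ro3_hbd`,
#'   `ro3_clogp` (per-criterion pass), `ro3_compliant` and
#'   `ro3_indeterminate`. `ro3_compliant` is `NA` when any needed descriptor
#'   is missing.
#' @examples
#' rule_of_three(data.frame(mw = c(300, 301), hbd = c(3, 0), clogp = c(3, 0)))
#' @export
rule_of_three <- function(compounds, mw_max = 300, hbd_max = 3, clogp_max = 3) {
  check_columns(compounds, c("mw", "hbd", "clogp"), "compounds")
  out <- as_tibble(compounds)
  out$ro3_mw <- out$mw <= mw_max
  out$ro3_hbd <- out$hbd <= hbd_max
  out$ro3_clogp <- out$clogp <= clogp_max
  out$ro3_indeterminate <- is.na(out$ro3_mw) | is.na(out$ro3_hbd) | is.na(out$ro3_clogp)
  out$ro3_compliant <- out$ro3_mw & out$ro3_hbd & out$ro3_clogp
  # a definite failure stays FALSE even when another descriptor is missing
  definite_fail <- (!out$ro3_mw & !is.na(out$ro3_mw)) |
    (!out$ro3_hbd & !is.na(out$ro3_hbd)) |
    (!out$ro3_clogp & !is.na(out$ro3_clogp))
  out$ro3_compliant[definite_fail] <- FALSE
  out
}

#' Ligand efficiency
#'
#' Binding free energy per heavy atom, LE = -dG / HAC with
#' dG = RT ln(KD) in kcal/mol at the given temperature. A 1 M binder has
#' LE = 0; tighter binding or fewer heavy atoms increase LE.
#'
#' @param kd Equilibrium dissociation constant in M (vectorized).
#' @param heavy_atoms Heavy-atom count (vectorized, >= 1).
#' @param temperature Temperature in kelvin (default 298.15).
#' @return Ligand efficiency in kcal/mol per heavy atom.
#' @examples
#' ligand_efficiency(480e-6, 17) # ~0.27
#' @export
ligand_efficiency <- function(kd, heavy_atoms, temperature = 298.15) {
  if (any(!is.finite(kd) | kd <= 0)) abort("`kd` must be positive.")
  if (any(!is.finite(heavy_atoms) | heavy_atoms < 1)) {
    abort("`heavy_atoms` must be at least 1.")
  }
  R_kcal <- 0.0019872 # kcal mol^-1 K^-1
  -(R_kcal * temperature) * log(kd) / heavy_atoms
}

# fingerprints ---------------------------------------------------------------

#' Atom-pair fingerprints and Tanimoto similarity matrix
#'
#' Computes atom-pair descriptor sets for each compound and the pairwise
#' Tanimoto coefficient T(A, B) = |A n B| / |A u B| on those sets. The
#' Tanimoto statistic is computed here, so any fingerprinting backend that
#' returns a set of descriptor codes per compound can be plugged in; the
#' default backend generates atom-pair descriptors with ChemmineR from the
#' `smiles` column.
#'
#' @param compounds A data frame with columns `id` and `smiles`, or a named
#'   list of fingerprint sets when `fingerprints` is given directly.
#' @param fingerprints Optional named list of descriptor vectors (one per
#'   compound id) that bypasses the SMILES backend; useful for testing and
#'   for externally computed fingerprints.
#' @return A symmetric numeric matrix of Tanimoto coefficients with compound
#'   ids as dimnames. Compounds whose SMILES could not be parsed (or with
#'   empty fingerprints) are excluded and listed in the `excluded` attribute.
#' @examples
#' tanimoto_matrix(fingerprints = list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
tanimoto_matrix <- function(compounds = NULL, fingerprints = NULL) {
  if (is.null(fingerprints)) {
    check_columns(compounds, c("id", "smiles"), "compounds")
    fingerprints <- atom_pair_fingerprints(compounds$id, compounds$smiles)
  }
  excluded <- names(fingerprints)[vapply(fingerprints, length, 1L) == 0L]
  fingerprints <- fingerprints[vapply(fingerprints, length, 1L) > 0L]
  if (length(fingerprints) == 0) abort("no compounds with non-empty fingerprints")
  ids <- names(fingerprints)
  n <- length(ids)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- tanimoto(fingerprints[[i]], fingerprints[[j]])
      }
    }
  }
  attr(m, "excluded") <- excluded
  m
}

#' @rdname tanimoto_matrix
#' @param a,b Descriptor sets (any atomic vectors).
#' @export
tanimoto <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

atom_pair_fingerprints <- function(ids, smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort(paste(
      "atom-pair fingerprinting needs the ChemmineR package;",
      "alternatively pass precomputed `fingerprints`."
    ))
  }
  fps <- lapply(seq_along(smiles), function(i) {
    if (is.na(smiles[i]) || !nzchar(smiles[i])) return(numeric(0))
    tryCatch({
      sdf <- ChemmineR::smiles2sdf(setNames(smiles[i], ids[i]))
      apset <- ChemmineR::sdf2ap(sdf)
      unique(ChemmineR::ap(apset[[1]]))
    }, error = function(e) numeric(0))
  })
  setNames(fps, ids)
}

#' Single-linkage clustering of a similarity matrix
#'
#' Converts Tanimoto similarity to distance (1 - T), builds a single-linkage
#' dendrogram, and assigns cluster labels by cutting at the given distance
#' threshold: two compounds share a cluster when they are connected by a
#' chain of links each at distance at most `cut`.
#'
#' @param sim Symmetric similarity matrix with compound ids as dimnames
#'   (e.g. from [tanimoto_matrix()]).
#' @param cut Distance threshold in `[0, 1]` at which the dendrogram is cut.
#' @return A tibble with columns `id` and `cluster` (integer labels, ordered
#'   by first appearance).
#' @examples
#' m <- tanimoto_matrix(fingerprints = list(
#'   a = 1:4, b = 2:5, c = 100:104
#' ))
#' cluster_single_linkage(m, cut = 0.6)
#' @export
cluster_single_linkage <- function(sim, cut) {
  if (is.null(dim(sim)) || nrow(sim) == 0) abort("`sim` must be a non-empty matrix")
  check_number(cut, "cut", non_negative = TRUE)
  ids <- rownames(sim) %||% as.character(seq_len(nrow(sim)))
  if (nrow(sim) == 1) {
    return(tibble(id = ids, cluster = 1L))
  }
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "single")
  labels <- stats::cutree(hc, h = cut)
  # relabel in order of first appearance for determinism
  labels <- as.integer(factor(labels, levels = unique(labels)))
  tibble(id = ids, cluster = labels)
}
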