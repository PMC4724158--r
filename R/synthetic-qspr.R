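# Synthetic structure-property data with known noise, duplication, outlier
# and decomposition structure.  Molecules come from an enumerable family of
# substituted (hetero)aromatics and alkanes; the latent melting point is a
# deterministic function of composition features that are visible to
# SMILES-substring descriptors (linear terms plus a mild ring x nitrogen
# interaction), centered near the 155 degrees C median typical of mined
# patent data.

.mpminer_cache <- new.env(parent = emptyenv())

.qspr_scaffolds <- function() {
  data.frame(
    smi = c("", "c1ccccc1", "c1ccncc1", "c1cncnc1", "c1cccnc1",
            "c1ccc2ccccc2c1", "c1ccc(-c2ccccc2)cc1", "c1ccc(C)cc1",
            "c1ccc(N)cc1", "c1ccc(O)cc1", "c1ccc(Cl)cc1", "c1ccc(F)cc1",
            "c1ccc(Br)cc1", "c1ccc(OC)cc1", "c1ccc(C#N)cc1", "c1ccsc1",
            "c1ccoc1", "c1cc[nH]c1", "C1CCCCC1", "c1ccc2[nH]ccc2c1"),
    rings = c(0, 1, 1, 1, 1, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2),
    nN   = c(0, 0, 1, 2, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 1),
    nO   = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0),
    nHal = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

.qspr_terminals <- function() {
  data.frame(
    smi = c("", "O", "N", "Cl", "OC(=O)", "NC(=O)", "N#C"),
    nN = c(0, 0, 1, 0, 0, 1, 1), nO = c(0, 1, 0, 0, 2, 1, 0),
    nHal = c(0, 0, 0, 1, 0, 0, 0),
    acid = c(0, 0, 0, 0, 1, 0, 0), amide = c(0, 0, 0, 0, 0, 1, 0),
    stringsAsFactors = FALSE)
}

#' Enumerable synthetic molecule family
#'
#' Deterministic enumeration of terminal-group + alkyl-chain +
#' (hetero)aromatic-scaffold combinations, canonicalized and
#' de-duplicated, with composition features and the latent melting point
#' used by [generate_qspr()].  The result is cached for the session.
#'
#' @return data frame with columns `smiles` (canonical), `rings`, `nN`,
#'   `nO`, `nHal`, `chain`, `branched`, `acid`, `amide`, `mp_latent`.
#' @export
smiles_family <- function() {
  if (!is.null(.mpminer_cache$family)) return(.mpminer_cache$family)
  sc <- .qspr_scaffolds()
  tm <- .qspr_terminals()
  chains <- rbind(
    data.frame(k = 0:19, branched = 0),
    data.frame(k = 3:19, branched = 1))
  chain_smi <- function(k, br) {
    if (br == 0) strrep("C", k) else paste0("CC(C)", strrep("C", k - 3))
  }
  grid <- expand.grid(is = seq_len(nrow(sc)), it = seq_len(nrow(tm)),
                      ic = seq_len(nrow(chains)))
  grid <- grid[!(sc$smi[grid$is] == "" & chains$k[grid$ic] == 0), ]
  chain_str <- mapply(chain_smi, chains$k[grid$ic], chains$branched[grid$ic])
  fam <- data.frame(
    smiles = paste0(tm$smi[grid$it], chain_str, sc$smi[grid$is]),
    rings = sc$rings[grid$is],
    nN = sc$nN[grid$is] + tm$nN[grid$it],
    nO = sc$nO[grid$is] + tm$nO[grid$it],
    nHal = sc$nHal[grid$is] + tm$nHal[grid$it],
    chain = chains$k[grid$ic], branched = chains$branched[grid$ic],
    acid = tm$acid[grid$it], amide = tm$amide[grid$it],
    stringsAsFactors = FALSE)
  fam$smiles <- canonical_smiles(fam$smiles)
  fam <- fam[!is.na(fam$smiles), , drop = FALSE]
  fam <- fam[!duplicated(fam$smiles), , drop = FALSE]
  raw <- with(fam, 35 * rings + 15 * nN + 12 * nO + 8 * nHal + 42 * acid +
                48 * amide - 3.2 * chain - 9 * branched + 2.5 * rings * nN)
  fam$mp_latent <- raw - stats::median(raw) + 155
  rownames(fam) <- NULL
  .mpminer_cache$family <- fam
  fam
}

#' Configuration for the synthetic structure-property generator
#'
#' Defaults emulate the statistical regime of melting points mined from
#' patents: a per-measurement reproducibility of 35 degrees C, about 5.5
#' percent of compounds that decompose rather than melt (their median
#' shifted from 155 to 210 degrees C), a moderate rate of repeated
#' measurements, and rare gross outliers at five noise SDs.
#'
#' @param n_molecules number of distinct molecules.
#' @param sigma_noise measurement noise SD, degrees C.
#' @param duplicate_rate probability that a molecule carries repeated
#'   measurements.
#' @param outlier_rate per-observation probability of a gross outlier.
#' @param outlier_offset_sigma outlier offset in units of `sigma_noise`.
#' @param decomp_fraction fraction of decomposing molecules.
#' @param decomp_median_shift shift of the decomposing class, degrees C.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `qspr_config` list.
#' @export
qspr_config <- function(n_molecules = 2000, sigma_noise = 35,
                        duplicate_rate = 0.3, outlier_rate = 0.02,
                        outlier_offset_sigma = 5, decomp_fraction = 0.055,
                        decomp_median_shift = 55, seed = 1) {
  stopifnot(sigma_noise > 0, decomp_fraction >= 0, decomp_fraction < 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1)
  structure(list(n_molecules = n_molecules, sigma_noise = sigma_noise,
                 duplicate_rate = duplicate_rate, outlier_rate = outlier_rate,
                 outlier_offset_sigma = outlier_offset_sigma,
                 decomp_fraction = decomp_fraction,
                 decomp_median_shift = decomp_median_shift,
                 seed = as.integer(seed)),
            class = "qspr_config")
}

#' Generate a synthetic structure-property table
#'
#' One row per observation.  The observed value is the molecule's latent
#' melting point plus Gaussian noise; molecules selected for duplication
#' are re-observed with fresh noise; outlying observations are offset by
#' `outlier_offset_sigma * sigma_noise` with random sign; decomposing
#' molecules have their latent value shifted and are labeled.  Truth
#' columns (`mp_true`, `decomposes`, `is_outlier`) travel with the data.
#'
#' @param cfg a [qspr_config()].
#' @return data frame with one row per observation: `mol_id`, `smiles`,
#'   `mp_true`, `decomposes`, `is_outlier`, `mp_obs`, plus record columns
#'   (`low_c`, `high_c`, `qualifier`, `outcome`, `suspicious`,
#'   `raw_text`, `doc_id`, `paragraph_number`) interoperable with the
#'   curation functions.
#' @export
generate_qspr <- function(cfg = qspr_config()) {
  stopifnot(inherits(cfg, "qspr_config"))
  fam <- smiles_family()
  if (cfg$n_molecules > nrow(fam))
    stop(sprintf("family holds %d distinct molecules; asked for %d",
                 nrow(fam), cfg$n_molecules))
  set.seed(cfg$seed)
  pick <- sample(nrow(fam), cfg$n_molecules)
  mol <- fam[pick, , drop = FALSE]
  n <- nrow(mol)
  decomposes <- stats::runif(n) < cfg$decomp_fraction
  mp_true <- mol$mp_latent + ifelse(decomposes, cfg$decomp_median_shift, 0)

  n_obs <- 1L + ifelse(stats::runif(n) < cfg$duplicate_rate,
                       1L + stats::rpois(n, 1), 0L)
  mol_idx <- rep(seq_len(n), n_obs)
  m <- length(mol_idx)
  obs <- mp_true[mol_idx] + stats::rnorm(m, 0, cfg$sigma_noise)
  is_outlier <- stats::runif(m) < cfg$outlier_rate
  obs <- obs + ifelse(is_outlier,
                      sample(c(-1, 1), m, replace = TRUE) *
                        cfg$outlier_offset_sigma * cfg$sigma_noise, 0)
  obs <- round(obs, 1)
  data.frame(
    mol_id = mol_idx,
    smiles = mol$smiles[mol_idx],
    mp_true = mp_true[mol_idx],
    decomposes = decomposes[mol_idx],
    is_outlier = is_outlier,
    mp_obs = obs,
    low_c = obs, high_c = obs,
    qualifier = "none",
    outcome = ifelse(decomposes[mol_idx], "decompose", "melt"),
    suspicious = FALSE,
    raw_text = sprintf("m.p. %.1f °C", obs),
    doc_id = sprintf("US%07d", seq_len(m)),
    paragraph_number = seq_len(m),
    stringsAsFactors = FALSE)
}
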