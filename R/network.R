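# Species and reaction enumeration for the LCK/CSK trans-phosphorylation
# network.  Every phosphorylation goes through an explicit enzyme-substrate
# dimer (Michaelis-Menten mechanism): association with a shared k_on,
# pair-specific dissociation (k_off) and catalysis (k_cat), the latter
# releasing the substrate phosphorylated at the bound site.  No cis
# reactions, no phosphatases.

free_lck_name <- function(form, dead = FALSE) {
  paste0(ifelse(dead, "Ld_", "L_"), form)
}

dimer_name <- function(enz_form, enz_dead, sub_form, sub_dead, site,
                       enzyme_is_csk = FALSE) {
  enz <- if (enzyme_is_csk) "CSK" else free_lck_name(enz_form, enz_dead)
  paste0(enz, ":", free_lck_name(sub_form, sub_dead), ".", site)
}

#' Enumerate the species of the LCK/CSK reaction network
#'
#' @param include_dead Include catalytically dead LCK (phosphorylatable,
#'   binds, never catalyzes) as a second competence class.
#' @param dead_policy How dead LCK participates: \code{"binder"} (default) --
#'   dead LCK is a substrate on all four of its sites \emph{and} occupies the
#'   enzyme role as an unproductive binder (same k_on/k_off, k_cat = 0);
#'   \code{"substrate_only"} -- dead LCK never occupies the enzyme role.
#' @param csk \code{"full"} (CSK species and its two substrate dimers),
#'   \code{"species_only"} (CSK declared but forms no dimers; the inactive-LCK
#'   validation variant), or \code{"none"}.
#' @return A data.frame of species in a fixed, deterministic order: free
#'   active LCK (UU, PU, UP, PP), free dead LCK, free CSK, LCK-LCK dimers in
#'   pair-table order (competence combinations nested within pair), CSK-LCK
#'   dimers.  Columns identify kind, phospho-forms, competences and bound
#'   site.
#' @export
#' @examples
#' nrow(enumerate_species())                      # 23
#' nrow(enumerate_species(TRUE, csk = "species_only"))  # 73
enumerate_species <- function(include_dead = FALSE,
                              dead_policy = c("binder", "substrate_only"),
                              csk = c("full", "species_only", "none")) {
  dead_policy <- match.arg(dead_policy)
  csk <- match.arg(csk)
  sp <- list()
  add <- function(id, kind, enz_form = NA, enz_dead = NA, sub_form = NA,
                  sub_dead = NA, site = NA, pair = NA) {
    sp[[length(sp) + 1L]] <<- data.frame(
      id = id, kind = kind, enz_form = enz_form, enz_dead = enz_dead,
      sub_form = sub_form, sub_dead = sub_dead, site = site, pair = pair,
      stringsAsFactors = FALSE)
  }
  for (f in LCK_FORMS)
    add(free_lck_name(f), "free_lck", sub_form = f, sub_dead = FALSE)
  if (include_dead)
    for (f in LCK_FORMS)
      add(free_lck_name(f, TRUE), "free_lck", sub_form = f, sub_dead = TRUE)
  if (csk != "none") add("CSK", "free_csk")

  pairs <- lck_pairs()
  lck <- pairs[pairs$enzyme != "CSK", ]
  for (i in seq_len(nrow(lck))) {
    enz_dead_opts <- if (include_dead && dead_policy == "binder")
      c(FALSE, TRUE) else FALSE
    sub_dead_opts <- if (include_dead) c(FALSE, TRUE) else FALSE
    for (ed in enz_dead_opts) for (sd in sub_dead_opts)
      add(dimer_name(lck$enzyme[i], ed, lck$sub_form[i], sd, lck$site[i]),
          "lck_lck_dimer", enz_form = lck$enzyme[i], enz_dead = ed,
          sub_form = lck$sub_form[i], sub_dead = sd, site = lck$site[i],
          pair = lck$pair[i])
  }
  if (csk == "full") {
    cskp <- pairs[pairs$enzyme == "CSK", ]
    for (i in seq_len(nrow(cskp))) {
      sub_dead_opts <- if (include_dead) c(FALSE, TRUE) else FALSE
      for (sd in sub_dead_opts)
        add(dimer_name(NA, FALSE, cskp$sub_form[i], sd, cskp$site[i],
                       enzyme_is_csk = TRUE),
            "csk_lck_dimer", enz_form = "CSK", enz_dead = FALSE,
            sub_form = cskp$sub_form[i], sub_dead = sd, site = cskp$site[i],
            pair = cskp$pair[i])
    }
  }
  out <- do.call(rbind, sp)
  rownames(out) <- NULL
  out
}

#' Number of distinct dimer species between one molecule each of two forms
#'
#' A dimer is identified by which unphosphorylated site of one member is
#' occupied by the other member's catalytic domain; e.g. the pair
#' (U394U505, P394U505) supports three dimers (Y394 and Y505 of U394U505
#' bound by P394U505, Y505 of P394U505 bound by U394U505).
#'
#' @param form_a,form_b Phospho-form labels (\code{"UU"}, \code{"PU"},
#'   \code{"UP"}, \code{"PP"}).
#' @return Integer count.
#' @export
count_pair_dimers <- function(form_a, form_b) {
  p <- lck_pairs()
  p <- p[p$enzyme != "CSK", ]
  sum((p$enzyme == form_a & p$sub_form == form_b) |
        (p$enzyme == form_b & p$sub_form == form_a & form_a != form_b))
}

#' Enumerate the mass-action reactions of a species list
#'
#' Every dimer contributes exactly three unidirectional reactions:
#' association (shared \code{k_on} or \code{k_on_csk}), dissociation (the
#' pair's \code{k_off}) and catalysis (the pair's \code{k_cat}; forced to
#' zero when the enzyme molecule is catalytically dead), which releases the
#' enzyme and the substrate phosphorylated at the bound site.
#'
#' @param species Data.frame from \code{\link{enumerate_species}}.
#' @return Data.frame of reactions with 1-based species indices
#'   \code{r1,r2} (reactants; \code{r2 = NA} for unimolecular),
#'   \code{p1,p2} (products), the rate-parameter name and a
#'   \code{rate_factor} (0 for dead-enzyme catalysis, else 1).
#' @export
enumerate_reactions <- function(species) {
  if (!all(species$kind %in%
             c("free_lck", "free_csk", "lck_lck_dimer", "csk_lck_dimer")))
    stop("unknown species kind: ",
         paste(setdiff(species$kind, c("free_lck", "free_csk",
                                       "lck_lck_dimer", "csk_lck_dimer")),
               collapse = ", "))
  pairs <- lck_pairs()
  idx_of <- stats::setNames(seq_len(nrow(species)), species$id)
  dimers <- which(species$kind %in% c("lck_lck_dimer", "csk_lck_dimer"))
  rx <- vector("list", 3L * length(dimers))
  n <- 0L
  for (d in dimers) {
    s <- species[d, ]
    is_csk <- s$kind == "csk_lck_dimer"
    e_id <- if (is_csk) "CSK" else free_lck_name(s$enz_form, s$enz_dead)
    sub_id  <- free_lck_name(s$sub_form, s$sub_dead)
    prod_id <- free_lck_name(phosphorylate(s$sub_form, s$site), s$sub_dead)
    pr <- pairs[pairs$pair == s$pair, ]
    kon_name <- if (is_csk) "k_on_csk" else "k_on"
    add <- function(type, r1, r2, p1, p2, rate_name, rate_factor) {
      n <<- n + 1L
      rx[[n]] <<- data.frame(
        type = type, pair = s$pair, dimer = s$id,
        r1 = idx_of[[r1]], r2 = if (is.na(r2)) NA_integer_ else idx_of[[r2]],
        p1 = idx_of[[p1]], p2 = if (is.na(p2)) NA_integer_ else idx_of[[p2]],
        rate_name = rate_name, rate_factor = rate_factor,
        stringsAsFactors = FALSE)
    }
    add("association",  e_id, sub_id, s$id, NA, kon_name, 1)
    add("dissociation", s$id, NA, e_id, sub_id, pr$koff_name, 1)
    add("catalysis",    s$id, NA, e_id, prod_id, pr$kcat_name,
        if (isTRUE(s$enz_dead)) 0 else 1)
  }
  out <- do.call(rbind, rx[seq_len(n)])
  rownames(out) <- NULL
  out
}

# Dense stoichiometry matrix (n_species x n_reactions).
stoich_matrix <- function(species, reactions) {
  S <- matrix(0, nrow(species), nrow(reactions),
              dimnames = list(species$id, NULL))
  for (j in seq_len(nrow(reactions))) {
    r <- reactions[j, ]
    S[r$r1, j] <- S[r$r1, j] - 1
    if (!is.na(r$r2)) S[r$r2, j] <- S[r$r2, j] - 1
    S[r$p1, j] <- S[r$p1, j] + 1
    if (!is.na(r$p2)) S[r$p2, j] <- S[r$p2, j] + 1
  }
  S
}

# Molecule-counting vectors: number of LCK molecules (resp. CSK molecules)
# contained in one unit of each species.  Conserved by every reaction.
conservation_vectors <- function(species) {
  lck <- ifelse(species$kind == "free_lck", 1,
                ifelse(species$kind == "lck_lck_dimer", 2,
                       ifelse(species$kind == "csk_lck_dimer", 1, 0)))
  csk <- ifelse(species$kind %in% c("free_csk", "csk_lck_dimer"), 1, 0)
  list(lck = stats::setNames(lck, species$id),
       csk = stats::setNames(csk, species$id))
}

#' Build the LCK/CSK reaction network
#'
#' Convenience constructor bundling species, reactions, stoichiometry and
#' conservation groups.  The active-only network has 23 species (4 free LCK,
#' free CSK, 16 LCK-LCK dimers, 2 CSK-LCK dimers) and 54 unidirectional
#' reactions.
#'
#' @inheritParams enumerate_species
#' @return List of class \code{"lck_network"}: \code{species},
#'   \code{reactions}, \code{stoich} (species x reactions),
#'   \code{conservation} (LCK- and CSK-counting vectors), and the builder
#'   flags.
#' @export
#' @examples
#' net <- lck_network()
#' nrow(net$species); nrow(net$reactions)  # 23, 54
lck_network <- function(include_dead = FALSE,
                        dead_policy = c("binder", "substrate_only"),
                        csk = c("full", "species_only", "none")) {
  dead_policy <- match.arg(dead_policy)
  csk <- match.arg(csk)
  species <- enumerate_species(include_dead, dead_policy, csk)
  reactions <- enumerate_reactions(species)
  structure(list(species = species, reactions = reactions,
                 stoich = stoich_matrix(species, reactions),
                 conservation = conservation_vectors(species),
                 include_dead = include_dead, dead_policy = dead_policy,
                 csk = csk),
            class = "lck_network")
}

#' @export
print.lck_network <- function(x, ...) {
  cat("LCK/CSK reaction network:", nrow(x$species), "species,",
      nrow(x$reactions), "reactions\n")
  cat("  dead LCK:", x$include_dead,
      if (x$include_dead) paste0("(policy: ", x$dead_policy, ")") else "",
      " CSK:", x$csk, "\n")
  invisible(x)
}

# Per-reaction rate constants under a parameter set.
reaction_rates <- function(network, params) {
  params <- rate_params(params)
  unname(params[network$reactions$rate_name]) * network$reactions$rate_factor
}

#' Mass-action time-derivative evaluator
#'
#' Returns the right-hand side of the ODE system: a function mapping
#' \code{(t, y)} (species densities, molecules/um^2) to the density
#' derivatives.  Pure R reference implementation; \code{\link{simulate_lck}}
#' uses an equivalent compiled evaluator.
#'
#' @param network An \code{lck_network}.
#' @param params An \code{lck_params} vector.
#' @return \code{function(t, y)} returning \code{dy/dt}.
#' @export
build_rhs <- function(network, params) {
  k  <- reaction_rates(network, params)
  r1 <- network$reactions$r1
  r2 <- network$reactions$r2
  bi <- !is.na(r2)
  r2f <- ifelse(bi, r2, 1L)   # dummy index; factor overwritten below
  S  <- network$stoich
  function(t, y) {
    f2 <- y[r2f]
    f2[!bi] <- 1
    v <- k * y[r1] * f2
    drop(S %*% v)
  }
}

# Encode a network + parameters into the flat numeric vector consumed by the
# compiled mass-action evaluator (src/lck_rhs.c).  Layout:
#   [1] n_species [2] n_reactions [3] n_stoich_entries
#   then k[1..nr], r1[1..nr] (0-based), r2[1..nr] (-1 = unimolecular),
#   then triplets (reaction0, species0, coef).
# Padded to a fixed length so the deSolve initializer can copy it.
LCK_PARMS_LEN <- 4096L

encode_network <- function(network, params) {
  k  <- reaction_rates(network, params)
  nr <- length(k)
  Sw <- which(network$stoich != 0, arr.ind = TRUE)
  coef <- network$stoich[Sw]
  enc <- c(nrow(network$species), nr, nrow(Sw),
           k, network$reactions$r1 - 1L,
           ifelse(is.na(network$reactions$r2), -1L,
                  network$reactions$r2 - 1L),
           as.numeric(rbind(Sw[, 2] - 1L, Sw[, 1] - 1L, coef)))
  if (length(enc) > LCK_PARMS_LEN)
    stop("network too large for the compiled evaluator")
  c(enc, numeric(LCK_PARMS_LEN - length(enc)))
}
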