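# Rule-based model text in a BNGL dialect.  The exporter writes molecule
# types, parameters, seed species and one bind/unbind/catalyze rule triplet
# per enzyme-substrate pair; the parser reads the species block back into a
# species table, so export -> parse round-trips the enumeration.

bngl_molecule <- function(form, dead, bond_cat = NA, bond_site = NA,
                          site = NA, with_act = FALSE) {
  y394 <- paste0("Y394~", substr(form, 1, 1))
  y505 <- paste0("Y505~", substr(form, 2, 2))
  if (!is.na(bond_site)) {
    if (site == "Y394") y394 <- paste0(y394, "!", bond_site)
    else y505 <- paste0(y505, "!", bond_site)
  }
  cat_c <- if (!is.na(bond_cat)) paste0("cat!", bond_cat) else "cat"
  act <- if (with_act) paste0(",act~", ifelse(dead, "0", "1")) else ""
  paste0("LCK(", cat_c, ",", y394, ",", y505, act, ")")
}

bngl_species_string <- function(s, with_act) {
  if (s$kind == "free_lck")
    return(bngl_molecule(s$sub_form, s$sub_dead, with_act = with_act))
  if (s$kind == "free_csk") return("CSK(cat)")
  sub <- bngl_molecule(s$sub_form, s$sub_dead, bond_site = 1, site = s$site,
                       with_act = with_act)
  enz <- if (s$kind == "csk_lck_dimer") "CSK(cat!1)"
  else bngl_molecule(s$enz_form, s$enz_dead, bond_cat = 1, with_act = with_act)
  paste0(enz, ".", sub)
}

#' Export a network as rule-based model text
#'
#' Writes a BNGL-dialect description: molecule types (LCK with phospho-sites
#' Y394/Y505 and, in the dead-LCK variant, a competence site \code{act};
#' CSK), the 38 rate parameters, the enumerated seed species and the
#' bind/unbind/catalyze rules.  \code{parse_bngl} reads the species block
#' back; export followed by parse yields an identical species list.
#'
#' @param network \code{lck_network}.
#' @param params Optional \code{lck_params} to embed in the parameters block
#'   (default: published medians).
#' @return Character scalar (the model text).
#' @export
export_bngl <- function(network, params = median_params()) {
  params <- rate_params(params)
  with_act <- network$include_dead
  sp <- network$species
  lines <- c("begin model",
             "begin parameters",
             sprintf("  %s %.15g", names(params), unname(params)),
             "end parameters",
             "begin molecule types",
             if (with_act) "  LCK(cat,Y394~U~P,Y505~U~P,act~1~0)"
             else "  LCK(cat,Y394~U~P,Y505~U~P)",
             if (network$csk != "none") "  CSK(cat)",
             "end molecule types",
             "begin species")
  for (i in seq_len(nrow(sp)))
    lines <- c(lines, sprintf("  %s  # %s", bngl_species_string(sp[i, ],
                                                               with_act),
                              sp$id[i]))
  lines <- c(lines, "end species", "begin reaction rules")
  rx <- network$reactions
  for (j in seq_len(nrow(rx))) {
    r <- rx[j, ]
    lhs <- if (r$type == "association")
      paste(sp$id[r$r1], "+", sp$id[r$r2]) else sp$id[r$r1]
    rhs <- if (r$type == "association") sp$id[r$p1]
    else paste(sp$id[r$p1], "+", sp$id[r$p2])
    lines <- c(lines, sprintf("  %s -> %s  %s  # %s pair %s", lhs, rhs,
                              r$rate_name, r$type, r$pair))
  }
  c_lines <- c(lines, "end reaction rules", "end model")
  paste(c_lines, collapse = "\n")
}

parse_bngl_molecule <- function(tok) {
  name <- sub("\\(.*", "", tok)
  comps <- strsplit(sub(".*\\((.*)\\)$", "\\1", tok), ",")[[1]]
  get_state <- function(prefix) {
    c_ <- comps[startsWith(comps, prefix)]
    if (!length(c_)) return(NA_character_)
    sub("!.*", "", sub(paste0(prefix, "~"), "", c_))
  }
  bonded <- function(prefix) any(grepl(paste0("^", prefix, "(~[A-Za-z0-9]+)?!"),
                                       comps))
  list(name = name,
       form = if (name == "LCK")
         paste0(get_state("Y394"), get_state("Y505")) else NA,
       dead = identical(get_state("act"), "0"),
       cat_bonded = bonded("cat"),
       site_bonded = if (bonded("Y394")) "Y394"
       else if (bonded("Y505")) "Y505" else NA_character_)
}

#' @rdname export_bngl
#' @param text Model text produced by \code{export_bngl}.
#' @return \code{parse_bngl} returns the species data.frame (same columns
#'   and order as \code{\link{enumerate_species}}).
#' @export
parse_bngl <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  a <- which(trimws(lines) == "begin species")
  b <- which(trimws(lines) == "end species")
  if (!length(a) || !length(b)) stop("no species block found")
  body <- trimws(sub("#.*", "", lines[(a + 1):(b - 1)]))
  body <- body[nzchar(body)]
  rows <- lapply(body, function(str) {
    mols <- lapply(strsplit(str, ".", fixed = TRUE)[[1]],
                   parse_bngl_molecule)
    if (length(mols) == 1) {
      m <- mols[[1]]
      if (m$name == "CSK")
        return(data.frame(id = "CSK", kind = "free_csk", enz_form = NA,
                          enz_dead = NA, sub_form = NA, sub_dead = NA,
                          site = NA, pair = NA, stringsAsFactors = FALSE))
      return(data.frame(id = free_lck_name(m$form, m$dead),
                        kind = "free_lck", enz_form = NA, enz_dead = NA,
                        sub_form = m$form, sub_dead = m$dead, site = NA,
                        pair = NA, stringsAsFactors = FALSE))
    }
    is_enz <- vapply(mols, function(m) m$cat_bonded, logical(1))
    enz <- mols[[which(is_enz)]]
    sub <- mols[[which(!is_enz)]]
    is_csk <- enz$name == "CSK"
    pairs <- lck_pairs()
    hit <- if (is_csk)
      pairs$enzyme == "CSK" & pairs$sub_form == sub$form &
        pairs$site == sub$site_bonded
    else pairs$enzyme == enz$form & pairs$sub_form == sub$form &
        pairs$site == sub$site_bonded
    data.frame(
      id = dimer_name(enz$form, enz$dead, sub$form, sub$dead,
                      sub$site_bonded, enzyme_is_csk = is_csk),
      kind = if (is_csk) "csk_lck_dimer" else "lck_lck_dimer",
      enz_form = if (is_csk) "CSK" else enz$form,
      enz_dead = enz$dead, sub_form = sub$form, sub_dead = sub$dead,
      site = sub$site_bonded, pair = pairs$pair[hit][1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
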