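SPECIES_LEVELS <- c("SOLUTE", "WATER", "CROWDER", "CATION", "ANION")

#' Build a topology from per-atom fields
#'
#' Low-level constructor used by [read_topology()] and the synthetic
#' generators.  Molecules are derived from residues: every non-solute residue
#' is one molecule; consecutive solute residues on the same chain are merged
#' into one molecule (a nucleic-acid strand).  Hydrogen--heavy bonding is
#' inferred by distance (< 1.2 Angstrom within a residue) from `positions`
#' when not supplied.
#'
#' @param name,resname,element character vectors, one entry per atom.
#' @param resid integer residue numbers.
#' @param species per-atom species, each one of
#'   `"SOLUTE" "WATER" "CROWDER" "CATION" "ANION"`.
#' @param charge partial charges (e); defaults to 0.
#' @param sigma,epsilon Lennard-Jones parameters (Angstrom, kcal/mol);
#'   default 0.
#' @param chain chain identifiers (used only to split solute molecules).
#' @param positions optional n x 3 coordinate matrix used for hydrogen-bond
#'   donor inference.
#' @param bonded_heavy optional index of the heavy atom bound to each
#'   hydrogen (NA for non-hydrogens); inferred from `positions` if missing.
#' @return an object of class `topology`: a list with elements `atoms`
#'   (data frame), `n_atoms`, `n_molecules` and `positions`.
#' @export
make_topology <- function(name, resname, resid, species,
                          element = NULL, charge = NULL,
                          sigma = NULL, epsilon = NULL,
                          chain = NULL, positions = NULL,
                          bonded_heavy = NULL) {
  n <- length(name)
  if (is.null(element)) element <- .guess_element(name)
  if (is.null(charge)) charge <- numeric(n)
  if (is.null(sigma)) sigma <- numeric(n)
  if (is.null(epsilon)) epsilon <- numeric(n)
  if (is.null(chain)) chain <- rep("A", n)
  species <- toupper(species)
  bad <- setdiff(unique(species), SPECIES_LEVELS)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "))

  ## residue boundaries -> molecule ids
  res_key <- cumsum(c(TRUE, resid[-1] != resid[-n] |
                        resname[-1] != resname[-n] |
                        chain[-1] != chain[-n]))
  res_species <- tapply(species, res_key, function(s) s[1])
  res_chain <- tapply(chain, res_key, function(s) s[1])
  n_res <- length(res_species)
  mol_of_res <- integer(n_res)
  m <- 0L
  for (r in seq_len(n_res)) {
    if (res_species[r] == "SOLUTE" && r > 1L &&
        res_species[r - 1L] == "SOLUTE" && res_chain[r] == res_chain[r - 1L]) {
      mol_of_res[r] <- mol_of_res[r - 1L]
    } else {
      m <- m + 1L
      mol_of_res[r] <- m
    }
  }
  mol_id <- mol_of_res[res_key]

  mixed <- tapply(species, mol_id, function(s) length(unique(s)) > 1)
  if (any(mixed)) stop("all atoms of one molecule must share one species")

  is_hydrogen <- element == "H"
  if (is.null(bonded_heavy)) {
    bonded_heavy <- rep(NA_integer_, n)
    if (!is.null(positions) && any(is_hydrogen)) {
      for (h in which(is_hydrogen)) {
        cand <- which(res_key == res_key[h] & !is_hydrogen)
        if (!length(cand)) next
        d <- sqrt(colSums((t(positions[cand, , drop = FALSE]) - positions[h, ])^2))
        j <- which.min(d)
        if (d[j] < 1.2) bonded_heavy[h] <- cand[j]
      }
    }
  }

  is_acceptor <- !is_hydrogen & element %in% c("N", "O", "F") &
    species %in% c("SOLUTE", "WATER", "CROWDER")
  is_donor_heavy <- rep(FALSE, n)
  hv <- bonded_heavy[is_hydrogen & !is.na(bonded_heavy)]
  is_donor_heavy[unique(hv)] <- element[unique(hv)] %in% c("N", "O", "F")

  atoms <- data.frame(
    index = seq_len(n), name = name, resname = resname, resid = resid,
    chain = chain, element = element, charge = charge,
    sigma = sigma, epsilon = epsilon, species = species,
    is_hydrogen = is_hydrogen, is_acceptor = is_acceptor,
    is_donor_heavy = is_donor_heavy, bonded_heavy = bonded_heavy,
    mol_id = mol_id, stringsAsFactors = FALSE)

  structure(list(atoms = atoms, n_atoms = n, n_molecules = max(mol_id),
                 positions = positions),
            class = "topology")
}

.guess_element <- function(name) {
  el <- sub("^[0-9']*", "", name)
  el <- substr(el, 1, 1)
  toupper(el)
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,", x$n_molecules, "molecules\n")
  cat("species:", paste(names(table(x$atoms$species)),
                        table(x$atoms$species), collapse = "  "), "\n")
  invisible(x)
}

#' Read a species / force-field parameter configuration
#'
#' The YAML file has three sections: `species_rules` (residue name to species
#' class), and optional `charges` and `lj` lists of records with fields
#' `resname`, `name`, and `charge` or `sigma`/`epsilon`.
#'
#' @param path YAML file path.
#' @return list with `species_rules` (named character) and `params`
#'   (data frame with resname, name, charge, sigma, epsilon).
#' @export
read_species_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- unlist(cfg$species_rules)
  params <- NULL
  to_df <- function(recs, val_cols) {
    do.call(rbind, lapply(recs, function(r)
      as.data.frame(r[c("resname", "name", val_cols)], stringsAsFactors = FALSE)))
  }
  ch <- if (!is.null(cfg$charges)) to_df(cfg$charges, "charge")
  lj <- if (!is.null(cfg$lj)) to_df(cfg$lj, c("sigma", "epsilon"))
  if (!is.null(ch) || !is.null(lj)) {
    params <- merge(
      if (is.null(ch)) lj[c("resname", "name")] else ch,
      if (is.null(lj)) ch[c("resname", "name")] else lj,
      by = c("resname", "name"), all = TRUE)
    params$charge <- if (is.null(params$charge)) 0 else ifelse(is.na(params$charge), 0, params$charge)
    params$sigma <- if (is.null(params$sigma)) 0 else ifelse(is.na(params$sigma), 0, params$sigma)
    params$epsilon <- if (is.null(params$epsilon)) 0 else ifelse(is.na(params$epsilon), 0, params$epsilon)
  }
  list(species_rules = rules, params = params)
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL only), assigns each residue a
#' species class from `species_rules`, and fills partial charges and
#' Lennard-Jones parameters from `param_table` (zeroes, with a warning, when
#' a parameter is missing).
#'
#' @param path PDB file.
#' @param species_rules named character vector mapping residue names to
#'   species classes, or the list returned by [read_species_config()].
#' @param param_table optional data frame with columns
#'   `resname, name, charge, sigma, epsilon`.
#' @param default_species species for residues absent from the rules
#'   (default `"SOLUTE"`, with a warning); pass `NULL` to make unmapped
#'   residues an error.
#' @return a [make_topology()] object.
#' @export
read_topology <- function(path, species_rules, param_table = NULL,
                          default_species = "SOLUTE") {
  if (is.list(species_rules) && !is.null(species_rules$species_rules)) {
    if (is.null(param_table)) param_table <- species_rules$params
    species_rules <- species_rules$species_rules
  }
  rec <- .read_pdb_records(path)
  a <- rec$atoms[rec$atoms$model == 1L, , drop = FALSE]
  if (!nrow(a)) stop("no ATOM records found in ", path)
  if (anyDuplicated(a$serial)) stop("duplicate atom indices in ", path)

  sp <- unname(species_rules[a$resname])
  if (anyNA(sp)) {
    missing_res <- unique(a$resname[is.na(sp)])
    if (is.null(default_species))
      stop("residue(s) not mapped to a species: ",
           paste(missing_res, collapse = ", "))
    warning("residue(s) ", paste(missing_res, collapse = ", "),
            " not in species rules; defaulting to ", default_species)
    sp[is.na(sp)] <- default_species
  }

  charge <- sigma <- epsilon <- numeric(nrow(a))
  if (!is.null(param_table)) {
    key <- paste(a$resname, a$name)
    pkey <- paste(param_table$resname, param_table$name)
    idx <- match(key, pkey)
    hit <- !is.na(idx)
    charge[hit] <- param_table$charge[idx[hit]]
    sigma[hit] <- param_table$sigma[idx[hit]]
    epsilon[hit] <- param_table$epsilon[idx[hit]]
    if (any(!hit))
      warning(sum(!hit), " atom(s) without parameters; charges/LJ set to 0")
  }

  pos <- as.matrix(a[, c("x", "y", "z")])
  make_topology(name = a$name, resname = a$resname, resid = a$resid,
                species = sp, element = a$element, charge = charge,
                sigma = sigma, epsilon = epsilon, chain = a$chain,
                positions = pos)
}
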