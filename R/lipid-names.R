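#' Lipid class registry
#'
#' The 16 lipid classes covered by the data model: 7 phospholipid
#' (sub)classes (PC, PE, PE O-, PE P-, PI, LPC, LPE), 5 sphingolipid classes
#' (SM, Cer, dhCer, HexCer, LacCer), 3 neutral glycerolipid classes
#' (MG, DAG, TAG) and cholesterol esters (CE). `n_chains` counts variable
#' fatty-acid residues per molecule; sphingolipid species additionally carry a
#' fixed sphingoid backbone (e.g. d18:1) that is not a variable fatty acid.
#'
#' @return data.frame with columns `code`, `group`, `n_chains`, `sphingoid`.
#' @export
lipid_classes <- function() {
  data.frame(
    code = c("CE", "MG", "DAG", "TAG",
             "Cer", "dhCer", "HexCer", "LacCer", "SM",
             "LPC", "LPE", "PC", "PE", "PE O-", "PE P-", "PI"),
    group = c("sterol ester", rep("neutral glycerolipid", 3),
              rep("sphingolipid", 5), rep("phospholipid", 7)),
    n_chains = c(1L, 1L, 2L, 3L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    sphingoid = c(rep(FALSE, 4), rep(TRUE, 5), rep(FALSE, 7)),
    stringsAsFactors = FALSE
  )
}

# classes whose molecules carry more than one variable fatty acid; only these
# are eligible for isobaric species aggregation
multi_fa_classes <- function() {
  cl <- lipid_classes()
  cl$code[cl$n_chains > 1L]
}

.class_synonyms <- c(
  "TG" = "TAG", "DG" = "DAG", "MAG" = "MG", "MAG." = "MG",
  "CER" = "Cer", "DCER" = "dhCer", "HCER" = "HexCer", "LCER" = "LacCer",
  "CHOLESTEROL ESTER" = "CE"
)

resolve_class <- function(token) {
  token <- trimws(token)
  cl <- lipid_classes()
  if (token %in% cl$code) return(token)
  up <- toupper(token)
  hit <- match(up, toupper(cl$code))
  if (!is.na(hit)) return(cl$code[hit])
  syn <- .class_synonyms[up]
  if (!is.na(syn)) return(unname(syn))
  stop(sprintf("unknown lipid class token '%s'", token), call. = FALSE)
}

chain_valid <- function(carbons, double_bonds) {
  carbons >= 12 && carbons <= 26 && double_bonds >= 0 && double_bonds <= 6
}

new_lipid_variable <- function(lipid_class, resolution, chains = NULL,
                               fatty_acid = NULL, total_carbons = NULL,
                               total_double_bonds = NULL, backbone = NULL) {
  v <- list(lipid_class = lipid_class, resolution = resolution,
            chains = chains, fatty_acid = fatty_acid,
            total_carbons = total_carbons,
            total_double_bonds = total_double_bonds, backbone = backbone)
  class(v) <- "lipid_variable"
  v
}

parse_cd <- function(txt, what = "fatty acid") {
  m <- regmatches(txt, regexec("^([0-9]+):([0-9]+)$", txt, perl = TRUE))[[1]]
  if (length(m) != 3L) {
    stop(sprintf("cannot parse %s composition '%s' (expected 'C:D')", what, txt),
         call. = FALSE)
  }
  c(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]))
}

#' Parse a lipid name into a structured variable
#'
#' Understands the shorthand grammar used throughout the package:
#' \itemize{
#'   \item molecular species: `"CE(16:0)"`, `"DAG(16:0/18:1)"`,
#'     `"TAG(16:0/18:1/18:2)"`, `"Cer(d18:1/24:0)"`, `"PE(P-16:0/20:4)"`;
#'   \item isobaric species (multi-fatty-acid classes only): `"TAG 52:2"`,
#'     `"PC 34:2"`, `"PE P-38:4"`;
#'   \item within-class fatty-acid sums: `"DAG(FA 16:0)"`, `"CE(FA 16:0)"`.
#' }
#' Sphingolipid backbones (`d`-prefixed first chain) are recorded but are not
#' variable fatty acids. Ether (`O-`) and plasmalogen (`P-`) first chains of
#' PE species promote the class to the `PE O-` / `PE P-` subclass.
#' For class fatty-acid sums, carbons must lie in 12-26 and double bonds in
#' 0-6.
#'
#' @param name character lipid name.
#' @return a `lipid_variable` object; `format()` on the result reproduces the
#'   canonical spelling (parse-format round trip).
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  name <- trimws(name)

  # CLASS(FA C:D) -> class fatty-acid sum
  m <- regmatches(name, regexec("^(.+?)\\(FA ([0-9]+:[0-9]+)\\)$", name, perl = TRUE))[[1]]
  if (length(m) == 3L) {
    cls <- resolve_class(m[2])
    cd <- parse_cd(m[3])
    if (!chain_valid(cd["carbons"], cd["double_bonds"])) {
      stop(sprintf("fatty acid '%s' outside the supported range (12-26 carbons, 0-6 double bonds)",
                   m[3]), call. = FALSE)
    }
    return(new_lipid_variable(cls, "class_fatty_acid_sum", fatty_acid = m[3]))
  }

  # CLASS(chain/chain/...) -> molecular species
  m <- regmatches(name, regexec("^(.+?)\\(([^)]+)\\)$", name, perl = TRUE))[[1]]
  if (length(m) == 3L) {
    cls <- resolve_class(m[2])
    chains <- trimws(strsplit(m[3], "/", fixed = TRUE)[[1]])
    backbone <- NULL
    # PE(O-16:0/...) / PE(P-16:0/...) -> ether / plasmalogen subclass
    if (cls == "PE" && grepl("^[OP]-", chains[1])) {
      cls <- paste0("PE ", substr(chains[1], 1, 2))
      chains[1] <- sub("^[OP]-", "", chains[1])
    }
    if (grepl("^d", chains[1])) {
      backbone <- chains[1]
      chains <- chains[-1]
      parse_cd(sub("^d", "", backbone), what = "sphingoid backbone")
    }
    reg <- lipid_classes()
    row <- reg[reg$code == cls, ]
    if (row$sphingoid && is.null(backbone)) {
      stop(sprintf("sphingolipid species '%s' must state a sphingoid backbone (e.g. d18:1)", name),
           call. = FALSE)
    }
    if (length(chains) != row$n_chains) {
      stop(sprintf("class %s expects %d fatty-acid chain(s), got %d in '%s'",
                   cls, row$n_chains, length(chains), name), call. = FALSE)
    }
    for (ch in chains) parse_cd(ch)
    fa <- if (row$n_chains == 1L) chains[1] else NULL
    return(new_lipid_variable(cls, "molecular_species", chains = chains,
                              fatty_acid = fa, backbone = backbone))
  }

  # PE O-38:4 / PE P-38:4 -> ether/plasmalogen isobaric species
  m <- regmatches(name, regexec("^PE ([OP]-)([0-9]+:[0-9]+)$", name, perl = TRUE))[[1]]
  if (length(m) == 3L) {
    cd <- parse_cd(m[3])
    return(new_lipid_variable(paste0("PE ", m[2]), "isobaric_species",
                              total_carbons = unname(cd["carbons"]),
                              total_double_bonds = unname(cd["double_bonds"])))
  }

  # CLASS C:D -> isobaric species
  m <- regmatches(name, regexec("^(.+?)[ -]?([0-9]+:[0-9]+)$", name, perl = TRUE))[[1]]
  if (length(m) == 3L) {
    tok <- trimws(sub("[ -]$", "", m[2]))
    cls <- resolve_class(tok)
    cd <- parse_cd(m[3])
    if (!(cls %in% multi_fa_classes())) {
      # one-FA classes: 'SM 16:0' is the molecular-species/FA-sum spelling
      if (!chain_valid(cd["carbons"], cd["double_bonds"])) {
        stop(sprintf("fatty acid '%s' outside the supported range", m[3]), call. = FALSE)
      }
      return(new_lipid_variable(cls, "class_fatty_acid_sum", fatty_acid = m[3]))
    }
    return(new_lipid_variable(cls, "isobaric_species",
                              total_carbons = unname(cd["carbons"]),
                              total_double_bonds = unname(cd["double_bonds"])))
  }

  stop(sprintf("cannot parse lipid name '%s'", name), call. = FALSE)
}

#' @export
format.lipid_variable <- function(x, ...) {
  switch(x$resolution,
    class_fatty_acid_sum = sprintf("%s(FA %s)", x$lipid_class, x$fatty_acid),
    isobaric_species = sprintf("%s%s%d:%d", x$lipid_class,
                               if (grepl("-$", x$lipid_class)) "" else " ",
                               x$total_carbons, x$total_double_bonds),
    molecular_species = {
      chains <- x$chains
      if (!is.null(x$backbone)) chains <- c(x$backbone, chains)
      if (x$lipid_class %in% c("PE O-", "PE P-")) {
        sprintf("PE(%s%s)", substr(x$lipid_class, 4, 5), paste(chains, collapse = "/"))
      } else {
        sprintf("%s(%s)", x$lipid_class, paste(chains, collapse = "/"))
      }
    },
    stop("unknown resolution")
  )
}

#' @export
print.lipid_variable <- function(x, ...) {
  cat(sprintf("<lipid_variable> %s [%s, %s]\n", format(x), x$lipid_class,
              x$resolution))
  invisible(x)
}

# variable fatty-acid chains of a molecular species (excludes the backbone)
species_fa_chains <- function(v) {
  stopifnot(v$resolution == "molecular_species")
  v$chains
}

# total carbons / double bonds across variable chains of a molecular species
species_totals <- function(v) {
  cds <- vapply(v$chains, parse_cd, c(carbons = 0, double_bonds = 0))
  c(carbons = as.integer(sum(cds["carbons", ])),
    double_bonds = as.integer(sum(cds["double_bonds", ])))
}
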