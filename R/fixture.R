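#' The archaeocyathan descriptor registry
#'
#' Builds the 120-slot descriptor registry used by the worked
#' archaeocyathan knowledge base: 85 descriptors of morphological and
#' ontogenetic data, 8 of stratigraphic and geographic data and 27 of
#' traditional classification data. Descriptor ids follow the published
#' numbering (`d6`, `d49`, ...) wherever the literature ties a number to a
#' meaning; the remaining slots are reserved placeholders with neutral
#' states, kept so that the registry arithmetic matches the real resource.
#'
#' Wall descriptions follow the standardized decomposition: every wall has
#' a carcass part (outer wall `d6`, `d11`–`d28`; inner wall `d7`,
#' `d31`–`d50`) and may have an additional sheath (`d52`–`d63`);
#' perforations, bumps, external plates and intervallar structures are
#' each broken into single-notion descriptors, with dependency rules
#' making detail descriptors inapplicable when the structure is absent.
#'
#' @return A list with `groups`, `descriptors` and `dependencies`, ready
#'   for [new_kb()].
#' @seealso [build_fixture()]
#' @export
archaeo_registry <- function() {
  groups <- list(
    mk_group("morphology", "morphological and ontogenetic data"),
    mk_group("stratigraphy", "stratigraphic and geographic data"),
    mk_group("classification", "traditional classification data")
  )

  cat_d <- function(id, label, states, group = "morphology",
                    taxonomic_value = TRUE) {
    # state ids are tokens; display labels read naturally
    states <- lapply(states, function(s) mk_state(s, gsub("_", " ", s)))
    mk_descriptor(id, label, "categorical", states = states,
                  group = group, taxonomic_value = taxonomic_value)
  }
  placeholder <- function(n, label_stem, group) {
    # neutral 2-4 state slots preserving the registry arithmetic
    k <- 2L + (n %% 3L)
    cat_d(paste0("d", n), sprintf("%s %d (reserved)", label_stem, n),
          paste0("s", seq_len(k)), group = group)
  }

  structure_states <- c("rudimentary", "simple", "basic", "concentrical")
  pore_shapes <- c("simple", "polygonal", "irregular", "subdivided")
  arrangements <- c("random", "linear", "quincuncial")
  plate_types <- c("spines", "bracts", "scales", "annuli")

  named <- list(
    cat_d("d1", "cup architecture",
          c("one_walled", "two_walled", "single_chambered", "multi_chambered",
            "chaetetid", "syringoid")),
    cat_d("d2", "chambers", c("present", "absent")),
    cat_d("d3", "habit", c("solitary", "modular")),
    cat_d("d6", "outer wall: carcass structure", structure_states),
    cat_d("d7", "inner wall: carcass structure", structure_states),
    cat_d("d11", "outer wall: carcass perforation type",
          c("pores", "canals", "none")),
    cat_d("d12", "outer wall: carcass pore shape", pore_shapes),
    cat_d("d15", "outer wall: pore distribution", c("regular", "irregular")),
    cat_d("d16", "outer wall: pore arrangement", arrangements),
    cat_d("d17", "outer wall: pore rows per intersept",
          c("one_row", "two_or_more")),
    cat_d("d18", "outer wall: canal porosity",
          c("non_porous", "porous", "spongiose")),
    cat_d("d19", "outer wall: canal shape", c("straight", "curved")),
    cat_d("d22", "outer wall: bumps", c("none", "present")),
    cat_d("d23", "outer wall: bump perforation", c("simple", "multiperforate")),
    cat_d("d24", "outer wall: bump opening direction", c("central", "downward")),
    cat_d("d25", "outer wall: external plates", c("none", "present")),
    cat_d("d26", "outer wall: external plate type", plate_types),
    cat_d("d27", "outer wall: external plate orientation",
          c("horizontal", "inclined")),
    cat_d("d28", "outer wall: morphological tubes", c("none", "present")),
    cat_d("d31", "inner wall: carcass perforation type",
          c("pores", "canals", "none"), taxonomic_value = FALSE),
    cat_d("d32", "inner wall: carcass pore shape", pore_shapes),
    cat_d("d33", "inner wall: pore rows per intersept",
          c("one_row", "two_or_more")),
    cat_d("d34", "inner wall: pore arrangement", arrangements),
    cat_d("d45", "inner wall: external plates", c("none", "present")),
    cat_d("d46", "inner wall: external plate type", plate_types),
    cat_d("d49", "inner wall: annuli stacking",
          c("aligned", "imbricated", "cone_in_cone")),
    cat_d("d51", "overall porosity aspect in section", c("coarse", "fine"),
          taxonomic_value = FALSE),
    cat_d("d52", "outer wall: additional sheath", c("absent", "present")),
    cat_d("d53", "additional sheath: type",
          c("microporous_sheath", "sieve", "mesh")),
    cat_d("d61", "additional sheath: mesh type",
          c("tabellae", "clathri", "pseudoclathri")),
    cat_d("d62", "additional sheath: type of sieves",
          c("incipient_pore_subdivision", "completely_subdivided")),
    cat_d("d65", "intervallum: vertical structures (adult stage)",
          c("none", "septa", "taeniae", "dictyonal_network")),
    cat_d("d66", "intervallum: vertical structures (early stage)",
          c("none", "septa", "taeniae", "dictyonal_network")),
    cat_d("d70", "intervallum: links between vertical structures",
          c("none", "synapticulae", "bars")),
    cat_d("d71", "intervallum: link repartition",
          c("each_interpore_node", "regular", "irregular")),
    cat_d("d79", "intervallum: tabulae", c("absent", "present")),
    cat_d("d80", "tabulae: construction",
          c("independent", "outer_wall_derived", "inner_wall_derived",
            "both_walls_derived")),
    cat_d("d81", "tabulae: porosity", c("imperforate", "porous"))
  )
  named_ids <- vapply(named, `[[`, "", "id")

  orders <- c("Monocyathida", "Ajacicyathida", "Capsulocyathida",
              "Coscinocyathida", "Archaeocyathida", "Kazachstanicyathida")
  suborders <- as.vector(t(outer(orders, c("A", "B"), paste, sep = "_")))

  classif <- list(
    cat_d("d94", "order", orders, group = "classification"),
    cat_d("d95", "suborder", suborders, group = "classification"),
    cat_d("d96", "traditional subdivision", c("regulares", "irregulares"),
          group = "classification")
  )
  strat <- list(
    cat_d("d86", "first occurrence (stage)",
          c("stage_2", "stage_3", "stage_4"), group = "stratigraphy"),
    cat_d("d87", "last occurrence (stage)",
          c("stage_2", "stage_3", "stage_4"), group = "stratigraphy")
  )

  descriptors <- c(named, strat, classif)
  have <- vapply(descriptors, `[[`, "", "id")
  for (n in 1:85) {
    id <- paste0("d", n)
    if (!id %in% have) {
      descriptors <- c(descriptors, list(placeholder(n, "morphological descriptor",
                                                     "morphology")))
    }
  }
  for (n in 86:93) {
    id <- paste0("d", n)
    if (!id %in% have) {
      descriptors <- c(descriptors, list(placeholder(n, "geographic descriptor",
                                                     "stratigraphy")))
    }
  }
  for (n in 94:120) {
    id <- paste0("d", n)
    if (!id %in% have) {
      descriptors <- c(descriptors, list(placeholder(n, "classification descriptor",
                                                     "classification")))
    }
  }
  # stable numeric order d1..d120
  num <- as.integer(sub("^d", "", vapply(descriptors, `[[`, "", "id")))
  descriptors <- descriptors[order(num)]

  dependencies <- list(
    mk_dependency("d12", "d11", "pores"),
    mk_dependency("d18", "d11", "canals"),
    mk_dependency("d19", "d11", "canals"),
    mk_dependency("d23", "d22", "present"),
    mk_dependency("d24", "d22", "present"),
    mk_dependency("d26", "d25", "present"),
    mk_dependency("d27", "d25", "present"),
    mk_dependency("d32", "d31", "pores"),
    mk_dependency("d46", "d45", "present"),
    mk_dependency("d49", "d46", "annuli"),
    mk_dependency("d53", "d52", "present"),
    mk_dependency("d61", "d53", "mesh"),
    mk_dependency("d62", "d53", "sieve"),
    mk_dependency("d71", "d70", c("synapticulae", "bars")),
    mk_dependency("d80", "d79", "present"),
    mk_dependency("d81", "d79", "present")
  )

  list(groups = groups, descriptors = descriptors, dependencies = dependencies)
}

#' The worked archaeocyathan fixture knowledge base
#'
#' A small knowledge base of fifteen archaeocyathan genera over the full
#' 120-descriptor registry, encoding the classical worked cases of
#' description comparison:
#'
#' * *Graphoscyphia*, *Dictyocyathus* and *Molybdocyathus* share an inner
#'   carcass wall with one row of simple pores per intersept and a
#'   dictyonal network; they differ only in outer carcass structure (basic
#'   vs rudimentary). The `pre_revision` variant codes *Dictyocyathus*
#'   with a basic outer carcass wall, as in the older literature, making
#'   it indistinguishable from *Graphoscyphia*; the `post_revision`
#'   variant codes it rudimentary, after re-examination of specimens,
#'   making it identical to *Molybdocyathus* (its junior synonym).
#' * *Coscinocyathus* (chambers, Capsulocyathida) and *Erismacoscinus*
#'   (no chambers, Ajacicyathida) look alike in transverse section, where
#'   chambers are invisible.
#' * *Taylorcyathus* and *Connanulofungia* differ only in how their inner
#'   wall annuli are stacked; the cone-in-cone state (`d49`) separates
#'   them.
#'
#' Cells not stated in the literature are left unknown. The classification
#' paths span the six orders and twelve suborders of the class; suborder
#' labels are schematic placeholders (`<Order>_A` / `<Order>_B`) since
#' only their number is fixed by the resource being modelled.
#'
#' @param variant `"post_revision"` (default) or `"pre_revision"`; the two
#'   differ only in the outer-carcass coding of *Dictyocyathus*.
#' @return A validator-clean knowledge base.
#' @examples
#' kb <- build_fixture()
#' checkbase(kb)$identical_pairs
#' @export
build_fixture <- function(variant = c("post_revision", "pre_revision")) {
  variant <- match.arg(variant)
  reg <- archaeo_registry()

  tx <- function(name, order, suborder) {
    mk_taxon(name, name, c(
      class = "Archaeocyatha", order = order,
      suborder = paste(order, suborder, sep = "_")))
  }
  st <- function(...) coding_states(...)

  taxa <- list(
    tx("Agastrocyathus", "Monocyathida", "A"),
    tx("Tumuliolynthus", "Monocyathida", "B"),
    tx("Erismacoscinus", "Ajacicyathida", "A"),
    tx("Dokidocyathus", "Ajacicyathida", "B"),
    tx("Coscinocyathus", "Capsulocyathida", "A"),
    tx("Tabulaconus", "Capsulocyathida", "B"),
    tx("Retecoscinus", "Coscinocyathida", "A"),
    tx("Taylorcyathus", "Coscinocyathida", "B"),
    tx("Connanulofungia", "Coscinocyathida", "B"),
    tx("Graphoscyphia", "Archaeocyathida", "A"),
    tx("Dictyocyathus", "Archaeocyathida", "A"),
    tx("Molybdocyathus", "Archaeocyathida", "A"),
    tx("Archaeocyathus", "Archaeocyathida", "B"),
    tx("Syringocyathus", "Kazachstanicyathida", "A"),
    tx("Eremitacyathus", "Kazachstanicyathida", "B")
  )

  # classification codings mirror each taxon's classification path
  class_codings <- function(order, suborder, subdivision) {
    list(d94 = st(order), d95 = st(paste(order, suborder, sep = "_")),
         d96 = st(subdivision))
  }
  trio_shared <- list(d31 = st("pores"), d32 = st("simple"),
                      d33 = st("one_row"), d65 = st("dictyonal_network"))
  tc_shared <- list(d1 = st("two_walled"), d6 = st("concentrical"),
                    d7 = st("concentrical"), d11 = st("pores"),
                    d12 = st("simple"), d45 = st("present"),
                    d46 = st("annuli"), d65 = st("septa"))

  descriptions <- list(
    Agastrocyathus = c(class_codings("Monocyathida", "A", "regulares"), list(
      d1 = st("one_walled"), d6 = st("simple"), d11 = st("pores"),
      d12 = st("simple"), d15 = st("regular"), d16 = st("random"))),
    Tumuliolynthus = c(class_codings("Monocyathida", "B", "regulares"), list(
      d1 = st("one_walled"), d6 = st("simple"), d11 = st("pores"),
      d22 = st("present"), d23 = st("simple"), d24 = st("downward"))),
    Erismacoscinus = c(class_codings("Ajacicyathida", "A", "regulares"), list(
      d1 = st("two_walled"), d2 = st("absent"), d6 = st("simple"),
      d11 = st("pores"), d12 = st("simple"), d15 = st("regular"),
      d22 = st("none"), d65 = st("septa"), d79 = st("present"),
      d80 = st("independent"), d81 = st("porous"))),
    Dokidocyathus = c(class_codings("Ajacicyathida", "B", "regulares"), list(
      d1 = st("two_walled"), d6 = st("rudimentary"), d65 = st("none"),
      d70 = st("none"), d71 = coding_inapplicable())),
    Coscinocyathus = c(class_codings("Capsulocyathida", "A", "regulares"), list(
      d1 = st("multi_chambered"), d2 = st("present"), d6 = st("simple"),
      d11 = st("pores"), d12 = st("simple"), d15 = st("regular"),
      d65 = st("septa"))),
    Tabulaconus = c(class_codings("Capsulocyathida", "B", "regulares"), list(
      d1 = st("multi_chambered"), d2 = st("present"), d6 = st("concentrical"),
      d79 = st("present"), d80 = st("both_walls_derived"),
      d81 = st("imperforate"))),
    Retecoscinus = c(class_codings("Coscinocyathida", "A", "regulares"), list(
      d1 = st("two_walled"), d6 = st("concentrical"), d11 = st("pores"),
      d12 = st("polygonal"), d15 = st("irregular"), d65 = st("septa"))),
    Taylorcyathus = c(class_codings("Coscinocyathida", "B", "regulares"),
                      tc_shared, list(d49 = st("aligned"))),
    Connanulofungia = c(class_codings("Coscinocyathida", "B", "regulares"),
                        tc_shared, list(d49 = st("cone_in_cone"))),
    Graphoscyphia = c(class_codings("Archaeocyathida", "A", "irregulares"),
                      trio_shared, list(d6 = st("basic"))),
    Dictyocyathus = c(class_codings("Archaeocyathida", "A", "irregulares"),
                      trio_shared,
                      list(d6 = st(if (variant == "pre_revision") "basic"
                                   else "rudimentary"))),
    Molybdocyathus = c(class_codings("Archaeocyathida", "A", "irregulares"),
                       trio_shared, list(d6 = st("rudimentary"))),
    Archaeocyathus = c(class_codings("Archaeocyathida", "B", "irregulares"), list(
      d1 = st("two_walled"), d6 = st("basic"), d31 = st("pores"),
      d32 = st("irregular"), d65 = st("taeniae"), d66 = st("taeniae"),
      d70 = st("synapticulae"), d71 = st("each_interpore_node"))),
    Syringocyathus = c(class_codings("Kazachstanicyathida", "A", "irregulares"), list(
      d1 = st("syringoid"), d11 = st("canals"), d18 = st("porous"),
      d19 = st("curved"))),
    Eremitacyathus = c(class_codings("Kazachstanicyathida", "B", "irregulares"), list(
      d1 = st("chaetetid"), d6 = st("basic"), d11 = st("pores"),
      d12 = st("subdivided"), d52 = st("present"),
      d53 = st("microporous_sheath")))
  )

  new_kb(
    metadata = list(
      name = paste0("archaeocyathan fixture (", variant, ")"),
      version = "1.0",
      license = "CC BY-NC-ND (structure modelled on the public resource)"),
    groups = reg$groups,
    descriptors = reg$descriptors,
    dependencies = reg$dependencies,
    taxa = taxa,
    descriptions = descriptions
  )
}
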