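mini_path <- system.file("extdata", "mini_model.xml", package = "cyanoflux")

test_that("SBML reader populates reactions, bounds, GPRs, subsystems", {
  m <- read_model(mini_path, format = "sbml_fbc")
  expect_equal(nrow(m$reactions), 3)
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(unname(reaction_bounds(m, "R_up")), c(-10, 0))
  expect_equal(unname(reaction_bounds(m, "R_conv")), c(0, 1000))
  expect_equal(m$reactions$subsystem[m$reactions$id == "R_conv"],
               "Central Metabolism")
  expect_equal(parse_gpr(m$reactions$gpr[m$reactions$id == "R_conv"]),
               parse_gpr("gA or (gB and gC)"))
  expect_setequal(m$genes, c("gA", "gB", "gC"))
  expect_equal(m$reactions$objective_coefficient[m$reactions$id == "R_bio"], 1)
  # stoichiometry: maximizing biomass drains the uptake fully
  expect_equal(fba_lp(m, "R_bio")$optimum, 10, tolerance = 1e-8)
})

test_that("model invariant violations raise, never warn", {
  met <- data.frame(id = c("A"), name = "", compartment = "c")
  rxn <- data.frame(id = c("R1", "R2"), name = "", subsystem = "",
                    lower_bound = c(0, 5), upper_bound = c(10, 3), gpr = "",
                    objective_coefficient = 0)
  S <- matrix(c(1, -1), 1)
  expect_error(metabolic_model("bad", met, rxn, character(0), S),
               "lower_bound > upper_bound.*R2")
  rxn2 <- rxn; rxn2$upper_bound <- 10; rxn2$id <- c("R1", "R1")
  expect_error(metabolic_model("bad", met, rxn2, character(0), S),
               "duplicate reaction id.*R1")
  rxn3 <- rxn; rxn3$upper_bound <- 10; rxn3$gpr <- c("gZ", "")
  expect_error(metabolic_model("bad", met, rxn3, character(0), S),
               "gene.*not in the model.*gZ")
})

test_that("JSON and SBML writers round-trip ids, bounds, GPRs, subsystems", {
  m <- make_toy_model("photo")
  for (writer in list(write_model_json, write_model_sbml)) {
    path <- tempfile(fileext = if (identical(writer, write_model_json))
      ".json" else ".xml")
    writer(m, path)
    m2 <- read_model(path)
    expect_equal(m2$reactions$id, m$reactions$id)
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_equal(m2$reactions$subsystem, m$reactions$subsystem)
    expect_equal(lapply(m2$reactions$gpr, parse_gpr),
                 lapply(m$reactions$gpr, parse_gpr))
    expect_setequal(m2$genes, m$genes)
    expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
    unlink(path)
  }
})

test_that("an independent SBML implementation agrees on our written model", {
  # cross-check the SBML writer/reader pair against the cobra/libsbml stack
  path <- tempfile(fileext = ".xml")
  write_model_sbml(make_toy_model("photo"), path)
  script <- paste(
    "import json, sys, cobra",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "print(json.dumps({r.id: [r.lower_bound, r.upper_bound] for r in m.reactions}))",
    sep = "; ")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(path)),
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  got <- jsonlite::fromJSON(out[length(out)])
  m <- make_toy_model("photo")
  expect_setequal(names(got), m$reactions$id)
  for (rid in m$reactions$id)
    expect_equal(got[[rid]], unname(reaction_bounds(m, rid)))
  unlink(path)
})

test_that("apply_condition overrides bounds without touching the input", {
  m <- make_toy_model("photo")
  expect_equal(apply_condition(m, condition_spec("noop")), m)

  sp <- condition_spec("low_uptake",
                       data.frame(reaction_id = "EX_CO2",
                                  lower_bound = -5, upper_bound = 0))
  m2 <- apply_condition(m, sp)
  expect_equal(unname(reaction_bounds(m2, "EX_CO2")), c(-5, 0))
  expect_equal(unname(reaction_bounds(m, "EX_CO2")), c(-10, 0))  # untouched
  expect_equal(apply_condition(m2, sp), m2)  # idempotent

  expect_error(apply_condition(m, condition_spec(
    "bad", data.frame(reaction_id = "NOPE", lower_bound = 0, upper_bound = 1))),
    "unknown reaction id.*NOPE")
  expect_error(condition_spec("bad", data.frame(
    reaction_id = "EX_CO2", lower_bound = 1, upper_bound = 0)),
    "lower_bound > upper_bound")
})

test_that("condition spec tables read back into per-condition specs", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("condition_id,reaction_id,lower_bound,upper_bound",
               "dark,EX_PHOTON,0,0",
               "dim,EX_PHOTON,-20,0",
               "dim,EX_CO2,-5,0"), path)
  specs <- read_condition_specs(path)
  expect_named(specs, c("dark", "dim"))
  expect_equal(nrow(specs$dim$bound_overrides), 2)
  m <- apply_condition(make_toy_model("photo"), specs$dark)
  expect_equal(unname(reaction_bounds(m, "EX_PHOTON")), c(0, 0))
  unlink(path)
})
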