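test_that("inventory CSVs parse with dot decimals and default dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_inventory_csv(path)
  inv <- read_inventory(path)
  expect_equal(nrow(inv), 3)
  expect_equal(inv$dbh, c(12.5, 33.1, 24.3))
  expect_equal(inv$height, c(14.2, 24.0, 21.5))
  expect_equal(unique(inv$forest_type), "varzea")
})

test_that("comma decimal separator is honoured", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plot_id;tree_tag;species;dbh_cm;height_m;forest_type",
    "P1;1;Mora paraensis;12,5;14,2;varzea"
  ), path)
  inv <- read_inventory(path, decimal_mark = ",")
  expect_equal(inv$dbh, 12.5)
  expect_equal(inv$height, 14.2)
})

test_that("rows with invalid DBH are rejected with a logged count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plot_id,tree_tag,species,dbh_cm,height_m,forest_type",
    "P1,1,Mora paraensis,-3,14.2,varzea",
    "P1,2,Mora paraensis,20,18.0,varzea",
    "P1,3,Mora paraensis,abc,10.0,varzea"
  ), path)
  expect_message(inv <- read_inventory(path), "Rejected 2 rows")
  expect_equal(nrow(inv), 1)
  expect_equal(attr(inv, "rejected"), 2)
})

test_that("genus falls back to the first token of the scientific name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plot_id,tree_tag,species,dbh_cm,height_m,forest_type",
    "P1,1,Mora paraensis,12.5,14.2,varzea"
  ), path)
  inv <- read_inventory(path)
  expect_equal(inv$genus, "Mora")
})

test_that("missing DBH column and empty file raise format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_id,tree_tag,height_m", "P1,1,14.2"), path)
  expect_error(read_inventory(path), "dbh_cm")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("plot_id,tree_tag,dbh_cm", path2)
  expect_error(read_inventory(path2), "no data rows")
})

test_that("write then read round-trips an inventory exactly", {
  inv <- tiny_inventory()
  path <- withr::local_tempfile(fileext = ".csv")
  write_inventory(inv, path)
  back <- read_inventory(path)
  for (col in c("plot_id", "tag", "family", "genus", "species",
                "dbh", "height", "forest_type")) {
    expect_equal(back[[col]], inv[[col]], info = col)
  }
})

test_that("wood-density tables average duplicates and precompute ranks", {
  df <- tibble::tibble(
    family = c("Fabaceae", "Fabaceae"), genus = c("Mora", "Mora"),
    species = c("Mora paraensis", "Mora paraensis"),
    wood_density = c(0.6, 0.8)
  )
  wd <- wood_density_table(df)
  expect_equal(wd$species$wood_density, 0.7)
  expect_equal(wd$genus$wood_density, 0.7)
  expect_equal(wd$family$wood_density, 0.7)
})

test_that("non-numeric wood density errors with the row index", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "family,genus,binomial,wood_density_g_cm3",
    "Fabaceae,Mora,Mora paraensis,abc"
  ), path)
  expect_error(read_wood_density(path), "row 1")
})

test_that("wood density assignment walks species -> genus -> family -> plot", {
  inv <- tibble::tibble(
    plot_id = "P1", tag = as.character(1:4),
    family = c("Fabaceae", "Fabaceae", "Lecythidaceae", "indet"),
    genus = c("Mora", "Mora", "Lecythis", "indet"),
    species = c("Mora paraensis", "Mora indet", "Lecythis indet", "indet"),
    dbh = c(10, 20, 30, 40), height = c(12, 18, 22, 25),
    forest_type = "varzea"
  )
  wd <- wood_density_table(tibble::tibble(
    family = c("Fabaceae", "Lecythidaceae"),
    genus = c("Mora", "Eschweilera"),
    species = c("Mora paraensis", "Eschweilera coriacea"),
    wood_density = c(0.86, 0.78)
  ))
  out <- assign_wood_density(inv, wd)
  expect_equal(out$wd_level, c("species", "genus", "family", "plot"))
  expect_equal(out$wood_density,
               c(0.86, 0.86, 0.78, mean(c(0.86, 0.86, 0.78))))
})

test_that("assignment is idempotent, never overwrites, and counts sum to n", {
  inv <- tiny_inventory()
  wd <- tiny_wd_table()
  once <- assign_wood_density(inv, wd)
  twice <- assign_wood_density(once, wd)
  expect_equal(twice$wood_density, once$wood_density)
  expect_true(all(twice$wd_level[!is.na(once$wood_density)] %in%
                    c("preset", once$wd_level)))
  rep <- wd_assignment_report(once)
  expect_equal(sum(rep$n), nrow(inv))
})

test_that("a plot with no resolvable trees is an error", {
  inv <- tibble::tibble(
    plot_id = "P9", tag = "1", family = "Unknownaceae", genus = "Novagenus",
    species = "indet", dbh = 10, height = 12, forest_type = "varzea"
  )
  expect_error(assign_wood_density(inv, tiny_wd_table()), "no basis")
})

test_that("unmatched trees in a plot with preset densities use the plot mean", {
  inv <- tiny_inventory()[1:3, ]
  inv$wood_density <- c(0.6, 0.8, NA)
  inv$species[3] <- "indet"
  inv$genus[3] <- "indet"
  inv$family[3] <- "indet"
  out <- assign_wood_density(inv, tiny_wd_table())
  expect_equal(out$wd_level[1:2], c("preset", "preset"))
  expect_equal(out$wood_density[3], 0.7)
})
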