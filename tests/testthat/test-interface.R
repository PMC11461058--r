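test_that("bundled configurations validate and match their advertised precision", {
    for (name in c("foraging_grid", "foraging_grid_controlled",
                   "knapping_tool_deterministic", "knapping_tool_uniform")) {
        cfg <- loadBundled(name)
        expect_true(validObject(configModel(cfg)))
        expect_true(validObject(configProcess(cfg)))
        expect_identical(configName(cfg), name)
    }
    kd <- configModel(loadBundled("knapping_tool_deterministic"))
    expect_identical(length(states(kd)), 3L)
    expect_identical(states(kd), c("rounded", "squared", "sharp"))
    expect_identical(
        normalizedPrecision(environmentalPrecision(kd, matrix = "A")), 1)
    expect_identical(
        normalizedPrecision(environmentalPrecision(kd, matrix = "B")), 1)

    ku <- configModel(loadBundled("knapping_tool_uniform"))
    expect_equal(normalizedPrecision(environmentalPrecision(ku, "A")), 0,
                 tolerance = 1e-12)
    expect_equal(normalizedPrecision(environmentalPrecision(ku, "B")), 0,
                 tolerance = 1e-12)

    fg <- configModel(loadBundled("foraging_grid"))
    expect_identical(length(states(fg)), 4L)
    expect_identical(likelihood(fg)["blue", "up-left"], 1)
    expect_identical(likelihood(fg)["yellow", "up-right"], 1)

    # alias and unknown names
    expect_identical(states(configModel(loadBundled("knapping_tool"))),
                     states(kd))
    expect_error(loadBundled("pottery"), "unknown bundled")
})

test_that("model JSON round-trips exactly and byte-identically", {
    m <- twoStateModel()
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    writeModel(m, f1)
    back <- readModel(f1)
    expect_identical(likelihood(back), likelihood(m))
    expect_identical(transitions(back), transitions(m))
    expect_identical(initialDist(back), initialDist(m))
    writeModel(back, f2)
    expect_identical(readLines(f1), readLines(f2))

    for (name in c("foraging_grid_controlled", "knapping_tool_uniform")) {
        cfg <- loadBundled(name)
        writeModel(configModel(cfg), f1)
        writeModel(readModel(f1), f2)
        expect_identical(readLines(f1), readLines(f2))
    }

    # process flag returns the environment-side class
    writeModel(mixedKnappingProcess(), f1)
    expect_s4_class(readModel(f1, process = TRUE), "GenerativeProcess")
    # malformed JSON is reported with the file name
    cat('{"name": "x"}', file = f1)
    expect_error(readModel(f1), "missing key")
})

test_that("labelled matrices round-trip through CSV", {
    A <- likelihood(mixedKnappingProcess())
    path <- withr::local_tempfile(fileext = ".csv")
    writeMatrixCSV(A, path)
    back <- readMatrixCSV(path)
    expect_identical(back, A)
})

test_that("trajectories round-trip through TSV", {
    traj <- simulateTrajectory(mixedKnappingProcess(), 25, seed = 6)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeTrajectory(traj, path)
    expect_identical(readTrajectory(path), traj)
})

test_that("the precision subcommand reports the deterministic panel", {
    out <- withr::local_tempfile(fileext = ".json")
    status <- runCLI(c("precision", "--bundled",
                       "knapping_tool_deterministic", "--matrix", "A",
                       "--out", out))
    expect_identical(status, 0L)
    rep <- jsonlite::read_json(out)
    expect_identical(rep$total_entropy, 0L)
    expect_identical(rep$normalized_precision, 1L)

    # same report from a bare matrix CSV
    csv <- withr::local_tempfile(fileext = ".csv")
    writeMatrixCSV(likelihood(configModel(
        loadBundled("knapping_tool_uniform"))), csv)
    status <- runCLI(c("precision", "--matrix-csv", csv, "--out", out))
    expect_identical(status, 0L)
    expect_equal(jsonlite::read_json(out)$total_entropy, 3 * log(3),
                 tolerance = 1e-12)
})

test_that("the simulate subcommand reproduces the foraging narrative", {
    out <- withr::local_tempfile(fileext = ".tsv")
    status <- runCLI(c("simulate", "--bundled", "foraging_grid",
                       "--steps", "2", "--seed", "17", "--out", out))
    expect_identical(status, 0L)
    traj <- readTrajectory(out)
    expect_identical(traj$state, c("up-left", "up-right"))
    expect_identical(traj$observation, c("blue", "yellow"))
})

test_that("generate and learn subcommands close the loop on a record file", {
    rec <- withr::local_tempfile(fileext = ".tsv")
    out <- withr::local_tempfile(fileext = ".json")
    proc <- withr::local_tempfile(fileext = ".json")
    writeModel(mixedKnappingProcess(), proc)
    expect_identical(runCLI(c("generate", "--process", proc,
                              "--sites", "50", "--periods", "8",
                              "--seed", "3", "--out", rec)), 0L)
    expect_identical(runCLI(c("learn", "--record", rec,
                              "--model", proc, "--out", out)), 0L)
    learned <- jsonlite::read_json(out)
    expect_identical(unlist(learned$states),
                     c("rounded", "squared", "sharp"))
    colsums <- vapply(learned$A, function(col) sum(unlist(col)), numeric(1))
    expect_true(all(abs(colsums - 1) < 1e-9))
    expect_true(learned$precision$A$total_entropy > 0)

    # learning from an empty record with zero priors cannot normalise
    empty <- withr::local_tempfile(fileext = ".tsv")
    writeRecord(artefactRecord(character(0), integer(0), character(0),
                               character(0)), empty)
    expect_identical(
        suppressMessages(runCLI(c("learn", "--record", empty,
                                  "--model", proc))), 1L)
})

test_that("salience and loop subcommands emit reports and traces", {
    out <- withr::local_tempfile(fileext = ".json")
    expect_identical(
        runCLI(c("salience", "--bundled", "foraging_grid_controlled",
                 "--out", out)), 0L)
    rep <- jsonlite::read_json(out)
    expect_identical(rep$selected_action, "move-up-left")
    expect_identical(length(rep$per_action_gain), 4L)

    trc <- withr::local_tempfile(fileext = ".tsv")
    expect_identical(
        runCLI(c("loop", "--bundled", "foraging_grid", "--steps", "3",
                 "--seed", "2", "--out", trc)), 0L)
    df <- utils::read.delim(trc)
    expect_identical(nrow(df), 3L)
    expect_identical(df$state, c("up-left", "up-right", "down-left"))

    # bad invocations fail with nonzero status, not crashes
    expect_identical(suppressMessages(runCLI(c("salience"))), 1L)
    expect_identical(suppressMessages(runCLI("excavate")), 1L)
    expect_identical(suppressMessages(runCLI(character(0))), 1L)
})
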