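# Replay stores shared across test files, built once per test session.

family_store <- local({
  dir <- file.path(tempdir(), "rfamtools-test-family-store")
  if (!dir.exists(dir)) build_family_fixtures(dir)
  dir
})

family_conn <- function() rfam_connection("replay", replay_dir = family_store)

case_study <- local({
  dir <- file.path(tempdir(), "rfamtools-test-casestudy-store")
  build_case_study(dir)
})

case_conn <- function() rfam_connection("replay", replay_dir = case_study$replay_dir)
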