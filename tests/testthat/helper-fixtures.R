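# Fixtures built in code: a small hand-written raw survey table and a
# long-format ACE trait simulator used across test files.

make_raw_fixture <- function() {
  data.frame(
    family_id = rep(1:3, each = 2),
    twin_index = rep(1:2, 3),
    zygosity = rep(c("MZ", "DZ", "MZ"), each = 2),
    sex = rep(c("female", "male", "female"), each = 2),
    age = rep(c(30, 50, 44), each = 2),
    race = rep(c("White", "White", "non-White"), each = 2),
    income = c(5, 6, 3, 3, 8, 7),
    education = c(3, 3, 2, 4, 5, 5),
    sleep_duration = c(8, 7.5, 6, 9, NA, 8.25),
    fruit_cat = c("5+", "3-4", "0", "1-2", "3-4", "1-2"),
    veg_cat = c("1-2", "1-2", "5+", "3-4", "3-4", "5+"),
    sedentary_cat = c("0h", "1-2h", "3-4h", "5+h", "1-2h", "3-4h"),
    vigorous_days = c(3, 0, 7, 2, 1, 0),
    moderate_days = c(3, 0, 7, 1, 2, 5),
    current_smoker = c(FALSE, FALSE, TRUE, FALSE, FALSE, NA),
    phq_item1 = c(0, 1, 3, 0, 2, 1),
    phq_item2 = c(0, 1, 3, 0, 1, 0),
    height = c(65, 65, 70, 72, 63, 100),
    weight = c(150, 140, 200, 180, 130, 0),
    stringsAsFactors = FALSE)
}

# long-format twin pairs with a single ACE-structured continuous trait
sim_trait_pairs <- function(n_mz, n_dz, a2, c2, e2, mu = 0, sd = 1) {
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  tr <- mu + sd * draw_ace_pair(zyg, a2, c2, e2)
  n <- n_mz + n_dz
  data.frame(family_id = rep(seq_len(n), 2),
             twin_index = rep(1:2, each = n),
             zygosity = rep(zyg, 2),
             y = c(tr[, 1], tr[, 2]))
}
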