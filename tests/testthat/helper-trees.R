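# Worked-example trees, built in code (the shipped split files mirror these).

fig1_t1 <- function() leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))
fig1_t2 <- function() leaf_tree(letters[1:5], "ab|cde")
fig2_t3 <- function() leaf_tree(c("a", "b", "c", "e"), "ab|ce")

fig4_t1 <- function() leaf_tree(letters[1:6], c("ab|cdef", "abc|def", "abcd|ef"))
fig4_t2 <- function() leaf_tree(letters[1:6], c("ab|cdef", "abc|def", "abce|df"))

fig6_t1 <- function() {
  leaf_tree(
    c(letters[1:8], "i"),
    c(
      "cd|abefghi", "bcd|aefghi", "abcd|efghi",
      "hi|abcdefg", "ghi|abcdef", "fghi|abcde"
    )
  )
}
fig6_t2 <- function() {
  leaf_tree(
    c(letters[1:8], "j"),
    c(
      "bc|adefghj", "abc|defghj", "abcd|efghj",
      "hj|abcdefg", "ghj|abcdef", "fghj|abcde"
    )
  )
}

fig12_t1 <- function() {
  leaf_tree(letters[1:8], c(
    "gh|abcdef", "fgh|abcde", "efgh|abcd", "aefgh|bcd", "abefgh|cd"
  ))
}
fig12_t2 <- function() {
  leaf_tree(letters[1:8], c(
    "fg|abcdeh", "dfg|abceh", "dfgh|abce", "defgh|abc", "adefgh|bc"
  ))
}

skey <- function(x) split_key(parse_split(x))

keyset <- function(t) sort(names(t$splits))

expect_same_splits <- function(t, keys) {
  expect_setequal(keyset(t), vapply(keys, skey, character(1)))
}
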