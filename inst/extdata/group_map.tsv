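# Breed-group assignment of the 14-animal cohort: high-milk-yield group
# (Sahiwal n=4, Gir n=4) vs low-milk-yield group (six animals, one each of
# Gaolao, Deoni, Pulikulam, Hallikar, Dangi, Amritmahal).
sample_id	group
Sahiwal 1	HIGH
Sahiwal 2	HIGH
Sahiwal 3	HIGH
Sahiwal 4	HIGH
Gir 1	HIGH
Gir 2	HIGH
Gir 3	HIGH
Gir 4	HIGH
Amritmahal	LOW
Dangi	LOW
Gaolao	LOW
Deoni	LOW
Pulikulam	LOW
Hallikar	LOW
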