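# French stop words (normalized forms are derived at load time)
le
la
les
un
une
des
de
du
au
aux
et
ou
en
dans
sur
pour
par
avec
sans
chez
ce
cette
ces
son
sa
ses
a
est
sont
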