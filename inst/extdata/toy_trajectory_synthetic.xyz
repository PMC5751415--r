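7
t= 0 ns
R1 3.317431548 3.006724618 2.967978999
R2 6.234010339 3.242874174 3.163264871
R3 2.889840141 5.777664253 3.246590702
R4 6.229911706 6.159438857 2.720434524
R5 3.105260727 3.237371140 5.855352347
L1 9.932944831 2.507840862 3.729648516
L2 10.029111919 5.706348347 3.785790376
7
t= 0.1 ns
R1 3.159818204 3.034462437 2.888794632
R2 6.253649380 3.109953245 3.092244401
R3 2.932417456 5.803572465 3.218257969
R4 6.293028249 6.129437241 2.732546912
R5 3.063523855 3.174794047 5.979181824
L1 9.925387588 2.546837578 3.673942779
L2 9.865377665 5.745535541 3.783069441
7
t= 0.2 ns
R1 3.286791788 3.044239964 3.008609507
R2 6.225910007 3.158049252 3.135958995
R3 2.803269669 5.741608011 3.111148844
R4 6.219909477 6.172981750 2.867501442
R5 3.044477653 3.155183836 5.959013961
L1 10.010456120 2.581771929 3.672904377
L2 9.931963509 5.734115322 3.830213492
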