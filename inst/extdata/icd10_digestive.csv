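code,term
C17.0,Duodenum
C17.1,Jejunum
C17.2,Ileum
C17.3,Meckel-Divertikel
C17.8,Duenndarm mehrere Teilbereiche ueberlappend
C17.9,Duenndarm nicht naeher bezeichnet
C18.0,Zaekum
C18.1,Appendix vermiformis
C18.2,Colon ascendens
C18.3,Flexura coli dextra
C18.4,Colon transversum
C18.5,Flexura coli sinistra
C18.6,Colon descendens
C18.7,Colon sigmoideum
C18.8,Kolon mehrere Teilbereiche ueberlappend
C18.9,Kolon nicht naeher bezeichnet
C19,Rektosigmoid
C20,Rektum
C21.0,Anus nicht naeher bezeichnet
C21.1,Analkanal
C21.2,Kloakenregion
C21.8,Rektum und Anus ueberlappend
C22.0,Leberzellkarzinom
C22.1,Intrahepatisches Gallengangskarzinom
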