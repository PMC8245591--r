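>integrase_like_synthetic synthetic stand-in exemplar for a phage integrase
ETVFHQQMKRPTCKKTKDRMFLHHFCDRMFPFPHNRREDSVDRFFSFTDIKTQRGNHGMD
RQLKSWPLCECPQYTLDKAFTRPIHRRKLTCHMATCAVMWEVFVYVMRLRLPHTNQWVIW
WIHMCQQGENCFQLFAFDVRWVFELAEKALEWLSGDFGLLQKYQYYKNGFNLKDLVLRDW
WIDIQFRLASQERGAGDYAAIAFQSPPQDDCHWKVSYDNDSWGRLAHPYTTSGLLRKNDP
LENAQTSGEQSNPRQRARWCMIQADYWNEHAMKFFEDFVL
>excisionase_like_synthetic synthetic stand-in exemplar for a phage excisionase
HQANMPPLHGWEYQTMFDAQSNVIPPINITWNQRAREYHDGLAGKVIEGVVQCGLNFPLH
YDLVEDIFVLQFGWDNGI
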