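   SW   perc perc perc  query     position in query              matching  repeat           position in repeat
score   div. del. ins.  sequence  begin  end          (left)     repeat    class/family   begin  end    (left)  ID

 1306    1.3  0.0  0.0  chr1      10001     10468 (248945954) +  LTR7Y     LTR/ERV1           1    468 (0)      1
  801   12.5  0.5  0.2  chr1      20100     21200 (248935222) C  MLT2A1    LTR/ERVL        1101      1 (0)      2
  512    5.0  0.1  0.0  chr1      35000     35900 (248920522) +  MER48     LTR/ERV1           1    901 (0)      3
  433   22.1  1.2  0.4  chr2      15000     16400 (242178529) C  MLT1B     LTR/ERVL-MaLR   1401      1 (0)      4
  950    0.9  0.0  0.0  chr2      50000     50800 (242144129) +  LTR7Y     LTR/ERV1           1    801 (0)      5
  300   18.0  0.3  0.1  chr2      70000     70500 (242124429) +  AluY      SINE/Alu           1    501 (0)      6
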